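country_code,year,factor,value
ALB,2000,gdp_pc,1126.7
ALB,2000,urban_pop_rate,41.7
ALB,2006,democracy_index,5.91
ALB,2000,renewable_water_pc,8652.0
ALB,2020,gdp_pc,5343.0
ALB,2020,urban_pop_rate,62.1
ALB,2020,democracy_index,6.08
ALB,2020,renewable_water_pc,9430.0
BGD,2000,gdp_pc,413.1
BGD,2000,urban_pop_rate,23.6
BGD,2006,democracy_index,6.11
BGD,2000,renewable_water_pc,816.0
BGD,2020,gdp_pc,1961.6
BGD,2020,urban_pop_rate,38.2
BGD,2020,democracy_index,5.99
BGD,2020,renewable_water_pc,636.0
BRA,2000,gdp_pc,3749.8
BRA,2000,urban_pop_rate,81.2
BRA,2006,democracy_index,7.38
BRA,2000,renewable_water_pc,31795.0
BRA,2020,gdp_pc,6923.7
BRA,2020,urban_pop_rate,87.1
BRA,2020,democracy_index,6.92
BRA,2020,renewable_water_pc,25782.0
ETH,2000,gdp_pc,124.5
ETH,2000,urban_pop_rate,14.7
ETH,2006,democracy_index,4.72
ETH,2000,renewable_water_pc,1843.0
ETH,2020,gdp_pc,936.3
ETH,2020,urban_pop_rate,21.7
ETH,2020,democracy_index,3.38
ETH,2020,renewable_water_pc,1062.0
IDN,2000,gdp_pc,870.6
IDN,2000,urban_pop_rate,42.0
IDN,2006,democracy_index,6.41
IDN,2000,renewable_water_pc,9521.0
IDN,2020,gdp_pc,3895.6
IDN,2020,urban_pop_rate,56.6
IDN,2020,democracy_index,6.30
IDN,2020,renewable_water_pc,7372.0
JPN,2000,gdp_pc,39173.0
JPN,2000,urban_pop_rate,78.6
JPN,2006,democracy_index,8.15
JPN,2000,renewable_water_pc,3399.0
JPN,2020,gdp_pc,39918.0
JPN,2020,urban_pop_rate,91.8
JPN,2020,democracy_index,8.13
JPN,2020,renewable_water_pc,3416.0
KEN,2000,gdp_pc,404.4
KEN,2000,urban_pop_rate,19.9
KEN,2006,democracy_index,5.08
KEN,2000,renewable_water_pc,656.0
KEN,2020,gdp_pc,1879.0
KEN,2020,urban_pop_rate,28.0
KEN,2020,democracy_index,5.05
KEN,2020,renewable_water_pc,386.0
MEX,2000,gdp_pc,7157.8
MEX,2000,urban_pop_rate,74.7
MEX,2006,democracy_index,6.67
MEX,2000,renewable_water_pc,4174.0
MEX,2020,gdp_pc,8655.0
MEX,2020,urban_pop_rate,80.7
MEX,2020,democracy_index,6.07
MEX,2020,renewable_water_pc,3204.0
NGA,2000,gdp_pc,567.9
NGA,2000,urban_pop_rate,34.8
NGA,2006,democracy_index,3.52
NGA,2000,renewable_water_pc,1808.0
NGA,2020,gdp_pc,2097.1
NGA,2020,urban_pop_rate,51.9
NGA,2020,democracy_index,4.10
NGA,2020,renewable_water_pc,1073.0
PER,2000,gdp_pc,1955.6
PER,2000,urban_pop_rate,73.0
PER,2006,democracy_index,6.11
PER,2000,renewable_water_pc,64234.0
PER,2020,gdp_pc,6126.9
PER,2020,urban_pop_rate,78.3
PER,2020,democracy_index,6.53
PER,2020,renewable_water_pc,51518.0
TUR,2000,gdp_pc,4337.5
TUR,2000,urban_pop_rate,64.7
TUR,2006,democracy_index,5.70
TUR,2000,renewable_water_pc,3582.0
TUR,2020,gdp_pc,8536.4
TUR,2020,urban_pop_rate,76.1
TUR,2020,democracy_index,4.48
TUR,2020,renewable_water_pc,2701.0
ZMB,2000,gdp_pc,345.6
ZMB,2000,urban_pop_rate,34.8
ZMB,2006,democracy_index,5.25
ZMB,2000,renewable_water_pc,8173.0
ZMB,2020,gdp_pc,958.4
ZMB,2020,urban_pop_rate,44.6
ZMB,2020,democracy_index,4.86
ZMB,2020,renewable_water_pc,4313.0
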