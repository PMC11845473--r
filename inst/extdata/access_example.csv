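country_code,country_name,year,service,area,ladder,rate
ALB,Albania,2000,drinking_water,total,at_least_basic,88.2
ALB,Albania,2000,drinking_water,total,safely_managed,51.0
ALB,Albania,2020,drinking_water,total,at_least_basic,95.1
ALB,Albania,2020,drinking_water,total,safely_managed,70.9
BGD,Bangladesh,2000,drinking_water,total,at_least_basic,94.1
BGD,Bangladesh,2000,drinking_water,total,safely_managed,52.0
BGD,Bangladesh,2020,drinking_water,total,at_least_basic,97.6
BGD,Bangladesh,2020,drinking_water,total,safely_managed,58.5
BRA,Brazil,2000,drinking_water,total,at_least_basic,93.1
BRA,Brazil,2000,drinking_water,total,safely_managed,76.9
BRA,Brazil,2020,drinking_water,total,at_least_basic,98.4
BRA,Brazil,2020,drinking_water,total,safely_managed,86.0
ETH,Ethiopia,2000,drinking_water,total,at_least_basic,18.6
ETH,Ethiopia,2000,drinking_water,total,safely_managed,4.2
ETH,Ethiopia,2020,drinking_water,total,at_least_basic,52.1
ETH,Ethiopia,2020,drinking_water,total,safely_managed,12.6
IDN,Indonesia,2000,drinking_water,total,at_least_basic,77.5
IDN,Indonesia,2000,drinking_water,total,safely_managed,20.1
IDN,Indonesia,2020,drinking_water,total,at_least_basic,92.6
IDN,Indonesia,2020,drinking_water,total,safely_managed,30.5
JPN,Japan,2000,drinking_water,total,at_least_basic,99.8
JPN,Japan,2000,drinking_water,total,safely_managed,97.6
JPN,Japan,2020,drinking_water,total,at_least_basic,99.9
JPN,Japan,2020,drinking_water,total,safely_managed,98.8
KEN,Kenya,2000,drinking_water,total,at_least_basic,46.6
KEN,Kenya,2000,drinking_water,total,safely_managed,21.5
KEN,Kenya,2020,drinking_water,total,at_least_basic,61.6
KEN,Kenya,2020,drinking_water,total,safely_managed,30.1
MEX,Mexico,2000,drinking_water,total,at_least_basic,89.3
MEX,Mexico,2000,drinking_water,total,safely_managed,48.1
MEX,Mexico,2020,drinking_water,total,at_least_basic,96.1
MEX,Mexico,2020,drinking_water,total,safely_managed,55.2
NGA,Nigeria,2000,drinking_water,total,at_least_basic,45.9
NGA,Nigeria,2000,drinking_water,total,safely_managed,15.1
NGA,Nigeria,2020,drinking_water,total,at_least_basic,75.4
NGA,Nigeria,2020,drinking_water,total,safely_managed,21.7
PER,Peru,2000,drinking_water,total,at_least_basic,79.6
PER,Peru,2000,drinking_water,total,safely_managed,41.0
PER,Peru,2020,drinking_water,total,at_least_basic,93.5
PER,Peru,2020,drinking_water,total,safely_managed,51.2
TUR,Turkiye,2000,drinking_water,total,at_least_basic,93.6
TUR,Turkiye,2000,drinking_water,total,safely_managed,82.1
TUR,Turkiye,2020,drinking_water,total,at_least_basic,99.0
TUR,Turkiye,2020,drinking_water,total,safely_managed,92.8
ZMB,Zambia,2000,drinking_water,total,at_least_basic,50.4
ZMB,Zambia,2000,drinking_water,total,safely_managed,17.2
ZMB,Zambia,2020,drinking_water,total,at_least_basic,65.4
ZMB,Zambia,2020,drinking_water,total,safely_managed,24.0
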