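test_that("percent rates are rescaled to proportions exactly once", {
  p <- write_fixture(c("country_code,year,service,area,ladder,rate",
                       "ALB,2000,drinking_water,total,at_least_basic,88.2"))
  a <- quiet(read_access_panel(p, access_dialect(unit = "percent")))
  expect_equal(nrow(a), 1L)
  expect_equal(a$rate, 0.882)
  expect_equal(a$country_code, "ALB")
})

test_that("out-of-range and malformed access rows error with a line number", {
  p <- write_fixture(c("country_code,year,service,area,ladder,rate",
                       "ALB,2000,drinking_water,total,at_least_basic,101.0"))
  expect_error(quiet(read_access_panel(p, access_dialect(unit = "percent"))),
               "out of range.*line 2")
  p2 <- write_fixture(c("country_code,year,service,area,ladder,rate",
                        "ALB,2000,drinking_water,total,not_a_ladder,50"))
  expect_error(quiet(read_access_panel(p2, access_dialect(unit = "percent"))),
               "malformed.*line 2")
  # ladder/service consistency
  p3 <- write_fixture(c("country_code,year,service,area,ladder,rate",
                        "ALB,2000,sanitation,total,surface_water,0.1"))
  expect_error(quiet(read_access_panel(p3)), "mismatch.*line 2")
})

test_that("duplicate access keys error; missing rates drop with a count", {
  p <- write_fixture(c("country_code,year,service,area,ladder,rate",
                       "ALB,2000,drinking_water,total,basic,0.2",
                       "ALB,2000,drinking_water,total,basic,0.3"))
  expect_error(quiet(read_access_panel(p)), "duplicate")
  p2 <- write_fixture(c("country_code,year,service,area,ladder,rate",
                        "ALB,2000,drinking_water,total,basic,0.2",
                        "DZA,2000,drinking_water,total,basic,"))
  a <- quiet(read_access_panel(p2))
  expect_equal(nrow(a), 1L)
  expect_equal(attr(a, "load_report")$records_dropped, 1L)
})

test_that("header-only file yields an empty panel and a zero-count report", {
  p <- write_fixture("country_code,year,service,area,ladder,rate")
  a <- quiet(read_access_panel(p))
  expect_equal(nrow(a), 0L)
  expect_equal(attr(a, "load_report")$records_read, 0L)
})

test_that("wide access dialect maps declared columns to ladder rows", {
  p <- write_fixture(c("iso,yr,alb,sm",
                       "KEN,2000,58.2,25.1",
                       "KEN,2020,71.7,40.0"))
  dia <- access_dialect(unit = "percent",
                        columns = c(country_code = "iso", year = "yr"),
                        value_columns = c(alb = "at_least_basic",
                                          sm = "safely_managed"),
                        service = "drinking_water", area = "total")
  a <- quiet(read_access_panel(p, dia))
  expect_equal(nrow(a), 4L)
  expect_setequal(a$ladder, c("at_least_basic", "safely_managed"))
  expect_equal(a$rate[a$ladder == "at_least_basic" & a$year == 2000], 0.582)
})

test_that("covariates load raw; non-positive log-factor values are excluded", {
  p <- write_fixture(c("country_code,year,factor,value",
                       "JPN,2020,gdp_pc,39918.0",
                       "JPN,2020,urban_pop_rate,91.8",
                       "XXX,2020,gdp_pc,-5"))
  expect_warning(cv <- suppressMessages(read_covariates(p)), "non-positive")
  expect_equal(nrow(cv), 2L)
  expect_equal(cv$value[cv$factor == "gdp_pc"], 39918.0)
  expect_equal(cv$value[cv$factor == "urban_pop_rate"], 91.8)  # raw scale
  p2 <- write_fixture(c("country_code,year,factor,value",
                        "JPN,2020,urban_pop_rate,140"))
  expect_error(quiet(read_covariates(p2)), "urban population rate")
})

test_that("democracy 2006 values are carried to 2000 without overwriting", {
  cv <- make_cov(data.frame(
    country_code = c("ALB", "ALB", "BEL", "BEL", "CAN"),
    year = c(2006L, 2020L, 2000L, 2006L, 2020L),
    factor = c("democracy_index", "gdp_pc", "democracy_index",
               "democracy_index", "democracy_index"),
    value = c(5.91, 6000, 9.1, 9.3, 9.0)))
  out <- suppressMessages(carry_democracy_2006_to_2000(cv))
  expect_equal(attr(out, "carried"), 1L)
  added <- out[out$country_code == "ALB" & out$year == 2000, ]
  expect_equal(added$value, 5.91)       # copy of the 2006 score
  expect_equal(out$value[out$country_code == "BEL" & out$year == 2000], 9.1)
  expect_false(any(out$country_code == "CAN" & out$year == 2000))
  # non-democracy records are never touched
  expect_equal(sum(out$factor != "democracy_index"),
               sum(cv$factor != "democracy_index"))
})

test_that("basic-or-higher aggregation follows the declared policy", {
  a1 <- make_access(data.frame(country_code = "AAA", year = 2000L,
                               service = "drinking_water",
                               ladder = c("safely_managed", "basic"),
                               rate = c(0.60, 0.25)))
  out <- aggregate_basic_or_higher(a1)
  expect_equal(out$rate[out$ladder == "basic_or_higher"], 0.85)

  # cumulative at_least_basic row wins over re-summing (no double count)
  a2 <- make_access(data.frame(country_code = "AAA", year = 2000L,
                               service = "drinking_water",
                               ladder = c("at_least_basic", "safely_managed",
                                          "basic"),
                               rate = c(0.85, 0.60, 0.25)))
  out2 <- aggregate_basic_or_higher(a2)
  expect_equal(out2$rate[out2$ladder == "basic_or_higher"], 0.85)
  out2b <- aggregate_basic_or_higher(a2, policy = "sum_components")
  expect_equal(out2b$rate[out2b$ladder == "basic_or_higher"], 0.85)

  # inconsistent ladder input: sum exceeding 1 names the key
  a3 <- make_access(data.frame(country_code = "BBB", year = 2000L,
                               service = "drinking_water",
                               ladder = c("safely_managed", "basic"),
                               rate = c(0.7, 0.4)))
  expect_error(aggregate_basic_or_higher(a3), "BBB.*inconsistent")
})

test_that("aggregation emits one row per complete key", {
  st <- tiny_study(n = 6)
  out <- aggregate_basic_or_higher(st$access)
  keys <- unique(st$access[, c("country_code", "year")])
  expect_equal(sum(out$ladder == "basic_or_higher"), nrow(keys))
})

test_that("result tables round-trip exactly through write/read", {
  tbl <- data.frame(parameter = c("C_d", "intercept"),
                    mean = c(-0.54, 1 / 3), cri_lower = c(-0.86, -0.22),
                    cri_upper = c(-0.22, sqrt(2)), rhat = c(1.001, 1.02),
                    significant = c(TRUE, FALSE), n_countries = c(147L, 147L),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_result_table(tbl, path)
  back <- read_result_table(path)
  expect_identical(back$mean, tbl$mean)          # bit-exact numerics
  expect_identical(back$cri_upper, tbl$cri_upper)
  expect_equal(back$significant, tbl$significant)

  # empty table -> header-only file
  write_result_table(tbl[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_result_table(path)), 0L)
})

test_that("panels round-trip through the canonical dialect", {
  st <- tiny_study(n = 5)
  pa <- tempfile(fileext = ".csv")
  pc <- tempfile(fileext = ".csv")
  write_access_panel(st$access, pa)
  write_covariate_panel(st$cov, pc)
  a <- quiet(read_access_panel(pa))
  cv <- quiet(read_covariates(pc))
  expect_equal(a$rate, st$access$rate)
  expect_equal(cv$value, st$cov$value)
  expect_equal(attr(a, "load_report")$records_dropped, 0L)
})
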