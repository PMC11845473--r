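# Small in-code fixtures shared across test files.

# hand-built long-format access panel: `rows` is a data.frame-ish list
make_access <- function(rows) {
  d <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(d$country_name)) d$country_name <- NA_character_
  if (is.null(d$area)) d$area <- "total"
  d <- d[, c("country_code", "country_name", "year", "service", "area",
             "ladder", "rate")]
  structure(d, class = c("wash_access", "data.frame"))
}

make_cov <- function(rows) {
  d <- as.data.frame(rows, stringsAsFactors = FALSE)
  structure(d[, c("country_code", "year", "factor", "value")],
            class = c("wash_cov", "data.frame"))
}

# a complete tiny study: n countries, 2 years, access at one ladder + the
# two component ladders, covariates for the three national factors
tiny_study <- function(n = 12, years = c(2000L, 2020L), seed = 99) {
  set.seed(seed)
  cc <- sprintf("T%02d", seq_len(n))
  cov <- do.call(rbind, lapply(years, function(y) {
    data.frame(country_code = rep(cc, 3), year = y,
               factor = rep(c("gdp_pc", "urban_pop_rate", "democracy_index"),
                            each = n),
               value = c(10^runif(n, 2.5, 4.8), runif(n, 20, 95),
                         runif(n, 1, 9.5)),
               stringsAsFactors = FALSE)
  }))
  acc <- do.call(rbind, lapply(years, function(y) {
    alb <- runif(n, 0.35, 0.99)
    sm <- alb * runif(n, 0.5, 0.9)
    data.frame(country_code = rep(cc, 3), country_name = NA_character_,
               year = y, service = "drinking_water", area = "total",
               ladder = rep(c("at_least_basic", "safely_managed", "basic"),
                            each = n),
               rate = c(alb, sm, alb - sm), stringsAsFactors = FALSE)
  }))
  list(access = make_access(acc), cov = make_cov(cov))
}

# write a delimited text fixture and return its path
write_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
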