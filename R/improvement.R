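#' Attributable proportion of recent improvement
#'
#' P2 = (C_later - C_prev) / C_later: the share of the later year's coverage
#' that was gained between the two years (0.5 means half of the
#' infrastructure in place at the later year was built in the interval).
#' Scale-invariant in the two rates; undefined (NA) when the later rate is
#' zero.
#'
#' @param c_prev,c_later access proportions at the earlier and later year.
#' @return numeric vector of P2 values (may be negative; `NA` where
#'   `c_later == 0`).
#' @examples
#' attributable_proportion(0.5, 0.8)  # 0.375
#' @export
attributable_proportion <- function(c_prev, c_later) {
  stopifnot(length(c_prev) == length(c_later))
  out <- ifelse(c_later == 0, NA_real_, (c_later - c_prev) / c_later)
  as.numeric(out)
}

#' Per-country improvement table
#'
#' Computes P2 for every country with the outcome observed in both years of
#' `year_pair` (area `"total"`: the improvement analysis never splits
#' urban/rural) and assigns a status: `included`,
#' `excluded_below_threshold` (P2 strictly below the threshold, reflecting
#' measurement error in an apparent coverage decline) or
#' `undefined_zero_denominator`.
#'
#' @param access an access panel (aggregate first for `basic_or_higher`).
#' @param service,quality outcome selection as in [build_dataset()].
#' @param year_pair the two years compared.
#' @param threshold exclusion threshold on P2 (strict `<`).
#' @return data frame of class `"improvement_table"`: `country_code`,
#'   `service`, `quality`, `c_prev`, `c_later`, `p2`, `status`.
#' @export
improvement_table <- function(access, service, quality,
                              year_pair = c(2000L, 2020L),
                              threshold = -0.05) {
  service <- match.arg(service, .services)
  a <- as.data.frame(access)
  a <- a[a$service == service & a$area == "total" & a$ladder == quality &
           a$year %in% year_pair, c("country_code", "year", "rate")]
  if (!nrow(a))
    stop("access panel has no total-area rows for ladder '", quality, "'")
  prev <- a[a$year == year_pair[1], c("country_code", "rate")]
  later <- a[a$year == year_pair[2], c("country_code", "rate")]
  names(prev)[2] <- "c_prev"
  names(later)[2] <- "c_later"
  d <- merge(prev, later, by = "country_code")
  d$service <- service
  d$quality <- quality
  d$p2 <- attributable_proportion(d$c_prev, d$c_later)
  d <- d[order(d$country_code),
         c("country_code", "service", "quality", "c_prev", "c_later", "p2")]
  rownames(d) <- NULL
  apply_exclusion(structure(d, class = c("improvement_table", "data.frame")),
                  threshold = threshold)
}

#' Apply the improvement exclusion rule
#'
#' Countries whose P2 is strictly below the threshold (default -0.05) are
#' flagged `excluded_below_threshold`; a P2 of exactly the threshold, or in
#' \[threshold, 0), is retained — such values enter the Gaussian likelihood
#' untouched even though the logistic mean cannot reach them. Undefined P2
#' (zero later-year coverage) is flagged `undefined_zero_denominator`. The
#' excluded countries are reported by code. Idempotent and
#' order-independent.
#'
#' @param table an improvement table (with `p2` computed).
#' @param threshold exclusion threshold (strict `<`).
#' @return the table with the `status` column (re)computed; excluded country
#'   codes attached as attribute `"excluded_countries"`.
#' @export
apply_exclusion <- function(table, threshold = -0.05) {
  d <- as.data.frame(table)
  d$status <- ifelse(is.na(d$p2), "undefined_zero_denominator",
                     ifelse(d$p2 < threshold, "excluded_below_threshold",
                            "included"))
  excl <- d$country_code[d$status == "excluded_below_threshold"]
  if (length(excl))
    message("[washbayes] excluded below threshold: ",
            paste(excl, collapse = ", "))
  structure(d, class = c("improvement_table", "data.frame"),
            excluded_countries = excl)
}

#' Period-mean covariates per country
#'
#' For each country and factor, applies the declared transform to every
#' annual value available in `years` and averages the transformed values
#' (`"transform_then_average"`, the default: for log-transformed series this
#' is a geometric-mean-type summary appropriate for right-skewed GDP and
#' water-resource data). The alternative `"average_then_transform"` is
#' offered as a sensitivity switch. Countries lacking any value for a factor
#' get `NA` for it.
#'
#' @param covariates a covariate panel.
#' @param factors a [factor_spec()].
#' @param years year range to average over.
#' @param policy averaging policy, see above.
#' @return data frame: `country_code`, one transformed-scale mean column per
#'   factor; per-factor availability counts as attribute `"n_years"`.
#' @export
mean_covariates <- function(covariates, factors = factor_spec(.factors[-2]),
                            years = 2000:2020,
                            policy = c("transform_then_average",
                                       "average_then_transform")) {
  policy <- match.arg(policy)
  cv <- as.data.frame(covariates)
  cv <- cv[cv$factor %in% factors$factor & cv$year %in% years, , drop = FALSE]
  out <- data.frame(country_code = sort(unique(cv$country_code)),
                    stringsAsFactors = FALSE)
  counts <- out
  for (i in seq_len(nrow(factors))) {
    f <- factors$factor[i]
    tr <- factors$transform[i]
    fi <- cv[cv$factor == f, , drop = FALSE]
    agg <- vapply(out$country_code, function(cc) {
      v <- fi$value[fi$country_code == cc]
      if (!length(v)) return(NA_real_)
      if (policy == "transform_then_average") mean(transform_factor(v, tr))
      else transform_factor(mean(v), tr)
    }, numeric(1))
    out[[f]] <- unname(agg)
    counts[[f]] <- vapply(out$country_code, function(cc)
      sum(fi$country_code == cc), integer(1))
  }
  structure(out, n_years = counts)
}

#' Assemble the improvement-regression dataset
#'
#' One row per included country: outcome P2 (from [improvement_table()] with
#' the exclusion rule applied) and z-scored period-mean covariates for all
#' requested factors (the default set is GDP, urban population rate,
#' democracy index and renewable water — every candidate factor). Countries
#' missing any factor mean are dropped with a warning. The dataset has no
#' year dummy; it is fitted with the same machinery as the access model.
#'
#' @inheritParams improvement_table
#' @param covariates a covariate panel.
#' @param factors a [factor_spec()]; defaults to all four factors.
#' @param mean_years years averaged for the covariates.
#' @param policy averaging policy of [mean_covariates()].
#' @param min_rows minimum included countries.
#' @return an [analysis_dataset()] with `x_dummy = NULL` and the
#'   improvement table attached as attribute `"improvement_table"`.
#' @export
build_improvement_dataset <- function(access, covariates, service, quality,
                                      factors = factor_spec(
                                        c("gdp_pc", "urban_pop_rate",
                                          "democracy_index",
                                          "renewable_water_pc")),
                                      year_pair = c(2000L, 2020L),
                                      mean_years = 2000:2020,
                                      threshold = -0.05,
                                      policy = "transform_then_average",
                                      min_rows = 10L) {
  tbl <- improvement_table(access, service, quality, year_pair, threshold)
  inc <- tbl[tbl$status == "included", , drop = FALSE]
  mc <- mean_covariates(covariates, factors, mean_years, policy)
  d <- merge(inc, mc, by = "country_code")
  cc <- complete.cases(d[, factors$factor, drop = FALSE])
  if (any(!cc))
    warning(sum(!cc), " country(ies) dropped: no covariate value in range")
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < min_rows)
    stop("only ", nrow(d), " included countries (< ", min_rows, ")")
  d <- d[order(d$country_code), , drop = FALSE]

  X <- matrix(NA_real_, nrow(d), nrow(factors),
              dimnames = list(NULL, factors$factor))
  norm <- factors
  norm$center <- NA_real_
  norm$scale <- NA_real_
  for (i in seq_len(nrow(factors))) {
    z <- zscore(d[[factors$factor[i]]])  # already transformed-scale means
    X[, factors$factor[i]] <- z$values
    norm$center[i] <- z$center
    norm$scale[i] <- z$scale
  }

  ds <- analysis_dataset(y = d$p2, X = X, x_dummy = NULL,
                         country = d$country_code, service = service,
                         quality = quality, area = "total",
                         years = as.integer(year_pair), normalization = norm)
  attr(ds, "improvement_table") <- tbl
  ds
}

#' Write an improvement table
#'
#' @param table an improvement table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_improvement_table <- function(table, path) {
  write_result_table(as.data.frame(table), path)
}
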