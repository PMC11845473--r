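#' Declare analysis factors and their transforms
#'
#' Right-skewed monetary and hydrological series (`gdp_pc`, `gdp_ppp_pc`,
#' `renewable_water_pc`) default to a log10 transform; `urban_pop_rate` and
#' `democracy_index` enter untransformed. Because every factor is z-scored
#' afterwards, the base of the logarithm is immaterial (a base change is an
#' affine rescaling absorbed by normalization), and `"log"` (natural) is
#' accepted as an equivalent declaration.
#'
#' @param factors character vector of factor names (subset of `gdp_pc`,
#'   `gdp_ppp_pc`, `urban_pop_rate`, `democracy_index`,
#'   `renewable_water_pc`).
#' @param transforms optional named character vector overriding the default
#'   transform (`"log10"`, `"log"` or `"identity"`) per factor.
#' @return data frame with columns `factor`, `transform`.
#' @export
factor_spec <- function(factors = c("gdp_pc", "urban_pop_rate",
                                    "democracy_index"),
                        transforms = NULL) {
  stopifnot(all(factors %in% .factors), !anyDuplicated(factors))
  tr <- ifelse(factors %in% .log_factors, "log10", "identity")
  names(tr) <- factors
  if (!is.null(transforms)) {
    stopifnot(all(names(transforms) %in% factors),
              all(transforms %in% c("log10", "log", "identity")))
    tr[names(transforms)] <- transforms
  }
  data.frame(factor = factors, transform = unname(tr),
             stringsAsFactors = FALSE)
}

#' Transform raw factor values
#'
#' @param values numeric vector; strictly positive under a log transform.
#' @param transform `"log10"`, `"log"` or `"identity"`.
#' @return transformed values.
#' @export
transform_factor <- function(values, transform = c("log10", "log",
                                                   "identity")) {
  transform <- match.arg(transform)
  if (transform != "identity" && any(values <= 0, na.rm = TRUE))
    stop("non-positive value under a log transform; ",
         "such records should have been excluded at read time")
  switch(transform,
         log10 = log10(values),
         log = log(values),
         identity = values)
}

#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to standard deviation 1 (n - 1 denominator),
#' returning the (center, scale) pair so the same normalization can be
#' reused and reported.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list with elements `values`, `center`, `scale`.
#' @export
zscore <- function(values) {
  if (length(values) < 2 || length(unique(values)) < 2)
    stop("cannot z-score a constant (zero-variance) input")
  ctr <- mean(values)
  scl <- sd(values)
  list(values = (values - ctr) / scl, center = ctr, scale = scl)
}

#' Construct an analysis dataset directly
#'
#' Low-level constructor for the stacked design consumed by [fit_model()].
#' Most users should call [build_dataset()] instead; this entry point exists
#' for simulation studies and degenerate cases (e.g. prior-only fits with
#' zero rows).
#'
#' @param y outcome vector (observed rates, or improvement proportions).
#' @param X numeric matrix of normalized covariate columns (may have zero
#'   columns).
#' @param x_dummy 0/1 year-dummy vector, or `NULL` for models without one.
#' @param country,year optional row identifiers.
#' @param service,quality,area,years optional descriptors carried along.
#' @param normalization optional data frame recording per-factor
#'   (transform, center, scale).
#' @return object of class `"analysis_dataset"`.
#' @export
analysis_dataset <- function(y, X, x_dummy = NULL, country = NULL,
                             year = NULL, service = NA_character_,
                             quality = NA_character_, area = NA_character_,
                             years = NULL, normalization = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X)) paste0("x", seq_len(ncol(X))) else character(0)
  if (!is.null(x_dummy)) {
    stopifnot(length(x_dummy) == length(y), all(x_dummy %in% c(0, 1)))
    x_dummy <- as.numeric(x_dummy)
  }
  n_per_year <- if (!is.null(year)) table(year) else NULL
  structure(list(y = as.numeric(y), X = X, x_dummy = x_dummy,
                 country = country, year = year, service = service,
                 quality = quality, area = area, years = years,
                 normalization = normalization,
                 n_countries_per_year = n_per_year),
            class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("<analysis_dataset> %d rows, %d factor(s)%s\n", length(x$y),
              ncol(x$X), if (!is.null(x$x_dummy)) " + year dummy" else ""))
  if (!is.na(x$service))
    cat(sprintf("  %s / %s / %s, years %s\n", x$service, x$quality, x$area,
                paste(x$years, collapse = "-")))
  invisible(x)
}

.cov_wide <- function(covariates, factors, years) {
  cv <- as.data.frame(covariates)
  cv <- cv[cv$factor %in% factors & cv$year %in% years, , drop = FALSE]
  out <- unique(cv[, c("country_code", "year")])
  for (f in factors) {
    fi <- cv[cv$factor == f, c("country_code", "year", "value")]
    names(fi)[3] <- f
    out <- merge(out, fi, by = c("country_code", "year"), all.x = TRUE)
  }
  out
}

#' Assemble the stacked two-year analysis dataset
#'
#' Filters the access panel to one (service, quality, area), stacks the rows
#' of the two years of `year_pair`, joins the requested covariates, keeps
#' complete cases, applies the declared transforms and then z-scores each
#' factor column. With `complete_unit = "country_year"` (default) a country
#' observed in only one year still contributes that row; `"country"`
#' restricts to countries complete in both years. Normalization is computed
#' over the pooled stacked rows by default (so the year dummy is a pure year
#' contrast on one common covariate scale), or per year.
#'
#' @param access an access panel containing rows for ladder `quality` (run
#'   [aggregate_basic_or_higher()] first for the aggregate category).
#' @param covariates a covariate panel.
#' @param service `"drinking_water"` or `"sanitation"`.
#' @param quality ladder level used as outcome (`"basic_or_higher"`,
#'   `"safely_managed"`, `"surface_water"`, `"open_defecation"`, ...).
#' @param area `"total"`, `"urban"` or `"rural"`.
#' @param year_pair two years `(y_prev, y_later)`; the dummy is 0 for the
#'   first, 1 for the second.
#' @param factors a [factor_spec()].
#' @param complete_unit `"country_year"` or `"country"`.
#' @param normalize `"pooled"` or `"per_year"`.
#' @param min_rows minimum complete rows below which assembly errors.
#' @return an [analysis_dataset()].
#' @export
build_dataset <- function(access, covariates, service, quality,
                          area = "total", year_pair = c(2000L, 2020L),
                          factors = factor_spec(),
                          complete_unit = c("country_year", "country"),
                          normalize = c("pooled", "per_year"),
                          min_rows = 10L) {
  complete_unit <- match.arg(complete_unit)
  normalize <- match.arg(normalize)
  service <- match.arg(service, .services)
  area <- match.arg(area, .areas)
  stopifnot(length(year_pair) == 2, year_pair[1] != year_pair[2])

  a <- as.data.frame(access)
  a <- a[a$service == service & a$area == area & a$year %in% year_pair, ,
         drop = FALSE]
  if (!any(a$ladder == quality))
    stop("access panel has no rows for ladder '", quality, "' (service ",
         service, ", area ", area, ")")
  a <- a[a$ladder == quality, c("country_code", "year", "rate")]

  d <- merge(a, .cov_wide(covariates, factors$factor, year_pair),
             by = c("country_code", "year"), all.x = TRUE)
  d <- d[complete.cases(d), , drop = FALSE]
  if (complete_unit == "country") {
    both <- names(which(table(d$country_code) == 2))
    d <- d[d$country_code %in% both, , drop = FALSE]
  }
  if (nrow(d) < min_rows)
    stop("only ", nrow(d), " complete rows (< ", min_rows,
         "); model not identifiable in practice")

  d <- d[order(match(d$year, year_pair), d$country_code), , drop = FALSE]

  X <- matrix(NA_real_, nrow(d), nrow(factors),
              dimnames = list(NULL, factors$factor))
  norm <- factors
  norm$center <- NA_real_
  norm$scale <- NA_real_
  for (i in seq_len(nrow(factors))) {
    f <- factors$factor[i]
    v <- transform_factor(d[[f]], factors$transform[i])
    if (normalize == "pooled") {
      z <- zscore(v)
      X[, f] <- z$values
      norm$center[i] <- z$center
      norm$scale[i] <- z$scale
    } else {
      for (yr in year_pair) {
        idx <- d$year == yr
        X[idx, f] <- zscore(v[idx])$values
      }
    }
  }

  analysis_dataset(y = d$rate, X = X,
                   x_dummy = as.numeric(d$year == year_pair[2]),
                   country = d$country_code, year = d$year,
                   service = service, quality = quality, area = area,
                   years = as.integer(year_pair), normalization = norm)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary least-squares
#' regression of column j on the remaining columns plus an intercept.
#' Perfect collinearity is reported as `Inf`, not an error.
#'
#' @param X numeric matrix of explanatory columns (include the year dummy to
#'   check it too); at least 3 rows, no constant column.
#' @return named numeric vector of VIF values.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows for VIF")
  if (any(apply(X, 2, function(v) length(unique(v)) < 2)))
    stop("VIF undefined for a constant column")
  if (ncol(X) < 2) return(setNames(1, colnames(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- 1 - sum(residuals(fit)^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' @importFrom stats residuals
NULL
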