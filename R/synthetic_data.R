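#' Scenario configuration for the synthetic country-panel generator
#'
#' Defaults emulate the study conditions of the cross-year analysis: 150
#' countries observed in 2000 and 2020; covariates drawn on the transformed
#' scale (log10 GDP per capita is normal, urban population rate and
#' democracy index are on their raw scales, log10 renewable water per
#' capita is normal) with a realistic positive correlation between wealth,
#' urbanization and democracy and a small upward drift of wealth and
#' urbanization over the period; access rates generated as
#' logistic(intercept + sum C_i z_i + C_d dummy) plus untruncated Gaussian
#' noise of standard deviation `sigma_obs` on the rate scale, with true
#' coefficients (2.0, 1.0, 0.3, 0.1) and year contrast -0.5.
#'
#' @param n_countries number of countries (>= 10).
#' @param years the panel years; the last is the dummy = 1 year.
#' @param service service the access rates belong to.
#' @param true_theta list(intercept, coef = named numeric over factors,
#'   c_d) — the generating coefficients on the z-scored covariate scale.
#' @param sigma_obs observation noise standard deviation on the rate scale.
#' @param covariate_model list with `means`, `sds` (transformed scale, per
#'   factor), `corr` (symmetric positive-definite correlation matrix) and
#'   `drift` (per-factor additive change applied per successive year in
#'   `years`).
#' @param missingness named per-factor probability that a country-year
#'   covariate value is missing.
#' @param emulate_democracy_gap if `TRUE`, democracy-index values for the
#'   first year are emitted at 2006 instead (no value at the first year), so
#'   the [carry_democracy_2006_to_2000()] path is exercised.
#' @param clip clip generated rates to \[0, 1\]; off by default so the data
#'   match the untruncated Gaussian observation model exactly and parameter
#'   recovery is unbiased.
#' @param seed integer seed.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_countries = 150L, years = c(2000L, 2020L),
                            service = "drinking_water",
                            true_theta = list(
                              intercept = 2.0,
                              coef = c(gdp_pc = 1.0, urban_pop_rate = 0.3,
                                       democracy_index = 0.1),
                              c_d = -0.5),
                            sigma_obs = 0.05,
                            covariate_model = NULL,
                            missingness = NULL,
                            emulate_democracy_gap = FALSE,
                            clip = FALSE, seed = 1L) {
  if (is.null(covariate_model)) covariate_model <- default_covariate_model()
  stopifnot(n_countries >= 10, length(years) >= 2, sigma_obs > 0)
  cm <- covariate_model
  stopifnot(isSymmetric(cm$corr),
            identical(rownames(cm$corr), names(cm$means)))
  if (inherits(try(chol(cm$corr), silent = TRUE), "try-error"))
    stop("covariate correlation matrix is not positive definite")
  if (is.null(missingness))
    missingness <- setNames(rep(0, length(cm$means)), names(cm$means))
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(years), service = service,
                 true_theta = true_theta, sigma_obs = sigma_obs,
                 covariate_model = cm, missingness = missingness,
                 emulate_democracy_gap = isTRUE(emulate_democracy_gap),
                 clip = isTRUE(clip), seed = as.integer(seed)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_covariate_model <- function() {
  f <- c("gdp_pc", "urban_pop_rate", "democracy_index",
         "renewable_water_pc")
  corr <- diag(4)
  dimnames(corr) <- list(f, f)
  corr["gdp_pc", "urban_pop_rate"] <- corr["urban_pop_rate", "gdp_pc"] <- 0.6
  corr["gdp_pc", "democracy_index"] <- corr["democracy_index", "gdp_pc"] <- 0.5
  corr["urban_pop_rate", "democracy_index"] <-
    corr["democracy_index", "urban_pop_rate"] <- 0.35
  list(
    # transformed scale: log10 $/cap, %, 0-10 index, log10 m3/cap
    means = c(gdp_pc = 3.7, urban_pop_rate = 55, democracy_index = 5.5,
              renewable_water_pc = 3.3),
    sds = c(gdp_pc = 0.6, urban_pop_rate = 20, democracy_index = 2.0,
            renewable_water_pc = 0.7),
    corr = corr,
    drift = c(gdp_pc = 0.2, urban_pop_rate = 5, democracy_index = 0,
              renewable_water_pc = -0.05)
  )
}

.back_transform <- function(value, f) {
  v <- if (f %in% .log_factors) 10^value else value
  if (f == "urban_pop_rate") v <- pmin(pmax(v, 0.1), 99.9)
  if (f == "democracy_index") v <- pmin(pmax(v, 0), 10)
  if (f %in% .log_factors) v <- pmax(v, 1e-6)
  v
}

#' Generate a synthetic covariate panel
#'
#' Draws one correlated vector per country per year on the transformed
#' scale, applies the per-year drift, back-transforms monetary and
#' hydrological factors to the raw scale (bounded factors are clamped to
#' their valid raw ranges), then applies per-factor missingness. Seeded and
#' fully deterministic.
#'
#' @param config a [scenario_config()].
#' @return a `wash_cov` covariate panel.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cm <- config$covariate_model
  f <- names(cm$means)
  L <- chol(cm$corr)
  set.seed(config$seed)
  countries <- sprintf("C%03d", seq_len(config$n_countries))
  rows <- list()
  for (yi in seq_along(config$years)) {
    yr <- config$years[yi]
    Zr <- matrix(rnorm(config$n_countries * length(f)), ncol = length(f))
    corr_draw <- Zr %*% L
    for (j in seq_along(f)) {
      mu <- cm$means[f[j]] + cm$drift[f[j]] * (yi - 1)
      raw <- .back_transform(mu + cm$sds[f[j]] * corr_draw[, j], f[j])
      keep <- runif(config$n_countries) >= config$missingness[f[j]]
      emit_year <- yr
      if (config$emulate_democracy_gap && f[j] == "democracy_index" &&
          yi == 1)
        emit_year <- 2006L
      rows[[length(rows) + 1]] <- data.frame(
        country_code = countries[keep], year = emit_year, factor = f[j],
        value = raw[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$factor, out$year, out$country_code), ]
  rownames(out) <- NULL
  structure(out, class = c("wash_cov", "data.frame"))
}

#' Generate a synthetic access panel from covariates
#'
#' For every country-year with all generating factors present, the access
#' rate is logistic(intercept + sum C_i z_i + C_d dummy) plus Gaussian noise
#' of sd `sigma_obs`, where z_i are the transformed covariates z-scored over
#' the stacked country-years — exactly the observation model the fitting
#' stage assumes. Ladder rows are emitted consistently with the aggregation
#' policy: `at_least_basic` carries the generated rate, `safely_managed` is
#' a country-specific fraction of it (equal to it where the noisy rate is
#' negative, preserving safely_managed <= at_least_basic), and `basic` is
#' the difference. Rates are not clipped to \[0, 1\] unless `config$clip`.
#'
#' @param covariates a covariate panel (typically from
#'   [generate_covariates()]).
#' @param config a [scenario_config()].
#' @return a `wash_access` panel (area `"total"`).
#' @export
generate_access <- function(covariates, config) {
  stopifnot(inherits(config, "scenario_config"))
  th <- config$true_theta
  fac <- names(th$coef)
  fs <- factor_spec(fac)
  if (config$emulate_democracy_gap && "democracy_index" %in% fac)
    covariates <- carry_democracy_2006_to_2000(covariates,
                                               to_year = config$years[1])
  wide <- .cov_wide(covariates, fac, config$years)
  wide <- wide[complete.cases(wide), , drop = FALSE]
  wide <- wide[order(wide$year, wide$country_code), , drop = FALSE]

  Z <- matrix(NA_real_, nrow(wide), length(fac),
              dimnames = list(NULL, fac))
  for (i in seq_along(fac))
    Z[, i] <- zscore(transform_factor(wide[[fac[i]]], fs$transform[i]))$values

  set.seed(config$seed + 1L)
  dummy <- as.numeric(wide$year == config$years[length(config$years)])
  eta <- th$intercept + drop(Z %*% th$coef) +
    (if (is.null(th$c_d)) 0 else th$c_d * dummy)
  rate <- logistic(eta) + rnorm(nrow(wide), 0, config$sigma_obs)
  if (config$clip) rate <- pmin(pmax(rate, 0), 1)

  frac <- runif(config$n_countries, 0.5, 0.9)
  names(frac) <- sprintf("C%03d", seq_len(config$n_countries))
  sm <- ifelse(rate >= 0, frac[wide$country_code] * rate, rate)

  mk <- function(ladder, r)
    data.frame(country_code = wide$country_code, country_name = NA_character_,
               year = wide$year, service = config$service, area = "total",
               ladder = ladder, rate = r, stringsAsFactors = FALSE)
  out <- rbind(mk("at_least_basic", rate), mk("safely_managed", unname(sm)),
               mk("basic", rate - unname(sm)))
  out <- out[order(out$ladder, out$year, out$country_code), ]
  rownames(out) <- NULL
  structure(out, class = c("wash_access", "data.frame"))
}

#' Generate a complete synthetic study
#'
#' Generates covariate and access panels under one scenario and, when `dir`
#' is given, writes them in the canonical dialect (`access.csv`,
#' `covariates.csv`) together with a key-value truth file (`truth.yaml`:
#' generating coefficients and noise sd) for test harnesses. Identical
#' config and seed produce byte-identical files.
#'
#' @param config a [scenario_config()].
#' @param dir optional output directory (created if needed).
#' @return list with `access`, `covariates`, `truth` (and `paths` when
#'   written).
#' @export
generate_study <- function(config = scenario_config(), dir = NULL) {
  cov <- generate_covariates(config)
  acc <- generate_access(cov, config)
  truth <- list(intercept = config$true_theta$intercept,
                coef = as.list(config$true_theta$coef),
                c_d = config$true_theta$c_d,
                sigma_obs = config$sigma_obs,
                seed = config$seed)
  out <- list(access = acc, covariates = cov, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(access = file.path(dir, "access.csv"),
                  covariates = file.path(dir, "covariates.csv"),
                  truth = file.path(dir, "truth.yaml"))
    write_access_panel(acc, paths$access)
    write_covariate_panel(cov, paths$covariates)
    yaml::write_yaml(truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Generate a synthetic improvement-regression dataset
#'
#' Draws period-mean covariates for `n_countries` (transform-then-averaged
#' over the scenario years and z-scored), then generates the improvement
#' outcome directly from its logistic regression with the scenario's
#' coefficients plus Gaussian noise — the generative counterpart of the
#' model fitted by [build_improvement_dataset()] + [fit_model()].
#'
#' @param config a [scenario_config()] whose `true_theta` has no `c_d`
#'   (any `c_d` is ignored) and whose `coef` names the improvement factors.
#' @return list with `dataset` (an [analysis_dataset()], no dummy) and
#'   `truth`.
#' @export
generate_improvement_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  th <- config$true_theta
  fac <- names(th$coef)
  fs <- factor_spec(fac)
  cov <- generate_covariates(config)
  mc <- mean_covariates(cov, fs, years = range(config$years)[1]:range(config$years)[2])
  mc <- mc[complete.cases(mc), , drop = FALSE]
  Z <- matrix(NA_real_, nrow(mc), length(fac), dimnames = list(NULL, fac))
  for (i in seq_along(fac)) Z[, i] <- zscore(mc[[fac[i]]])$values
  set.seed(config$seed + 2L)
  p2 <- logistic(th$intercept + drop(Z %*% th$coef)) +
    rnorm(nrow(mc), 0, config$sigma_obs)
  ds <- analysis_dataset(y = p2, X = Z, x_dummy = NULL,
                         country = mc$country_code,
                         quality = "synthetic_improvement")
  list(dataset = ds,
       truth = list(intercept = th$intercept, coef = th$coef,
                    sigma_obs = config$sigma_obs))
}
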