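#' Univariable factor screening
#'
#' Stage one of the analysis protocol: for each candidate factor, fit the
#' logistic-mean model with that single factor plus the year dummy, and flag
#' the factor "selected" when the 95% credible interval of its coefficient
#' excludes zero. The selected set feeds the multivariable stage.
#'
#' @param access,covariates harmonized panels (aggregate the ladder first
#'   for `basic_or_higher`).
#' @param service,quality,area,year_pair outcome selection as in
#'   [build_dataset()].
#' @param candidates a [factor_spec()] of candidate factors (default: all
#'   four — GDP per capita, urban population rate, democracy index,
#'   renewable water per capita).
#' @param spec a [model_spec()] used as template (its `factor_names` are
#'   overridden per factor).
#' @return data frame of class `"screening_table"`: one row per
#'   (factor, parameter) with posterior summaries, `n_countries`, and the
#'   per-factor `selected` flag.
#' @export
run_screening <- function(access, covariates, service, quality,
                          area = "total", year_pair = c(2000L, 2020L),
                          candidates = factor_spec(
                            c("gdp_pc", "urban_pop_rate", "democracy_index",
                              "renewable_water_pc")),
                          spec = model_spec()) {
  if (!nrow(candidates)) stop("empty candidate factor list")
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    f <- candidates$factor[i]
    ds <- build_dataset(access, covariates, service, quality, area,
                        year_pair, candidates[i, , drop = FALSE])
    sp <- spec
    sp$factor_names <- f
    sp$include_dummy <- TRUE
    fit <- fit_model(ds, sp)
    s <- fit_summary(fit)
    s <- s[s$parameter != "sigma", , drop = FALSE]
    s$factor <- f
    s$selected <- s$significant[s$parameter == f]
    rows[[f]] <- s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("factor", "parameter", "mean", "cri_lower", "cri_upper",
                 "rhat", "significant", "selected", "n_countries")]
  class(out) <- c("screening_table", "data.frame")
  out
}

#' Multivariable year-comparison fit
#'
#' Stage two: fit the logistic-mean model with all selected factors plus the
#' year dummy for one (service, quality, area) and year pair. The default
#' factor set is GDP per capita, urban population rate and democracy index
#' (the factors selected by screening on national data); area-specific
#' (urban/rural) runs add renewable water per capita as a fourth factor.
#' Variance inflation factors of the design (including the dummy) are
#' computed alongside.
#'
#' @inheritParams run_screening
#' @param factors a [factor_spec()]; `NULL` picks the default for `area`.
#' @param gdp_variant `"gdp_pc"` or `"gdp_ppp_pc"` — swapping to purchasing
#'   power parity replaces the GDP column, nothing structural.
#' @return list of class `"multivariable_run"`: `fit`, `summary`, `vif`,
#'   `dataset`.
#' @export
run_multivariable <- function(access, covariates, service, quality,
                              area = "total", year_pair = c(2000L, 2020L),
                              factors = NULL,
                              gdp_variant = c("gdp_pc", "gdp_ppp_pc"),
                              spec = model_spec()) {
  gdp_variant <- match.arg(gdp_variant)
  if (is.null(factors)) {
    base <- c(gdp_variant, "urban_pop_rate", "democracy_index")
    if (area != "total") base <- c(base, "renewable_water_pc")
    factors <- factor_spec(base)
  } else if (gdp_variant == "gdp_ppp_pc") {
    factors$factor[factors$factor == "gdp_pc"] <- "gdp_ppp_pc"
  }
  ds <- build_dataset(access, covariates, service, quality, area, year_pair,
                      factors)
  sp <- spec
  sp$factor_names <- factors$factor
  sp$include_dummy <- TRUE
  fit <- fit_model(ds, sp)
  vif <- compute_vif(cbind(ds$X, year_dummy = ds$x_dummy))
  structure(list(fit = fit, summary = fit_summary(fit), vif = vif,
                 dataset = ds),
            class = "multivariable_run")
}

#' Improvement regression run
#'
#' Stage three: compute the attributable proportion P2 per country between
#' the two years, apply the exclusion rule, regress P2 on z-scored
#' period-mean values of all four factors (no year dummy), and report the
#' improvement table, the fit and the excluded-country list.
#'
#' @inheritParams run_multivariable
#' @param mean_years years averaged for the covariates.
#' @param threshold P2 exclusion threshold (strict `<`).
#' @return list of class `"improvement_run"`: `table`, `fit`, `summary`,
#'   `excluded`, `dataset`.
#' @export
run_improvement <- function(access, covariates, service, quality,
                            year_pair = c(2000L, 2020L),
                            mean_years = 2000:2020, threshold = -0.05,
                            factors = factor_spec(
                              c("gdp_pc", "urban_pop_rate",
                                "democracy_index", "renewable_water_pc")),
                            spec = model_spec()) {
  ds <- build_improvement_dataset(access, covariates, service, quality,
                                  factors = factors, year_pair = year_pair,
                                  mean_years = mean_years,
                                  threshold = threshold)
  sp <- spec
  sp$factor_names <- factors$factor
  sp$include_dummy <- FALSE
  fit <- fit_model(ds, sp)
  tbl <- attr(ds, "improvement_table")
  structure(list(table = tbl, fit = fit, summary = fit_summary(fit),
                 excluded = attr(tbl, "excluded_countries"), dataset = ds),
            class = "improvement_run")
}

#' Descriptive ladder aggregation
#'
#' Population-weighted global summaries per year, service and ladder level:
#' the number of people with access (sum of rate x population over countries
#' with data) and the weighted global percentage. Countries with access data
#' but no population are excluded from the weighted sums with a warning.
#'
#' @param access an access panel (area `"total"`).
#' @param population data frame `country_code`, `year`, `population`.
#' @return data frame: `year`, `service`, `ladder`, `population_with_access`,
#'   `percent`.
#' @export
run_descriptive <- function(access, population) {
  a <- as.data.frame(access)
  a <- a[a$area == "total", , drop = FALSE]
  d <- merge(a, population, by = c("country_code", "year"), all.x = TRUE)
  nop <- is.na(d$population)
  if (any(nop)) {
    warning(length(unique(d$country_code[nop])),
            " country(ies) lack population data; excluded from weighting")
    d <- d[!nop, , drop = FALSE]
  }
  key <- interaction(d$year, d$service, d$ladder, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g)
    data.frame(year = g$year[1], service = g$service[1],
               ladder = g$ladder[1],
               population_with_access = sum(g$rate * g$population),
               percent = 100 * sum(g$rate * g$population) /
                 sum(g$population),
               stringsAsFactors = FALSE)))
  out <- out[order(out$service, out$ladder, out$year), ]
  rownames(out) <- NULL
  out
}

.stage_try <- function(label, expr, report) {
  res <- tryCatch(expr, error = function(e) {
    message("[washbayes] stage '", label, "' failed: ", conditionMessage(e))
    structure(list(message = conditionMessage(e)), class = "stage_error")
  })
  report$stages[[label]] <- if (inherits(res, "stage_error")) "error" else "ok"
  list(result = res, report = report)
}

#' Run a full configured analysis
#'
#' Orchestrates simulation/ingestion, harmonization (democracy carry,
#' basic-or-higher aggregation), the requested stages (screening,
#' multivariable, improvement, descriptive), and writes every table, the VIF
#' table per multivariable fit, convergence warnings and a machine-readable
#' manifest (config echo + seed + package version) under `outdir`. Stage
#' failures are logged and the remaining stages continue; the returned
#' report records per-stage status.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   `seed`; `outdir`; either `simulate` (arguments to [scenario_config()])
#'   or `inputs` (`access`, `covariates` paths plus optional dialect
#'   settings `unit`, `range`); optional `model` (overrides for
#'   [model_spec()]); `analyses`, a list of stage descriptors
#'   (`stage` = screening | multivariable | improvement | descriptive,
#'   plus `service`, `quality`, `area`, `year_pair`, `gdp_variant`, ...).
#' @param strict abort on the first stage failure instead of continuing.
#' @return run report list (per-stage status, output paths, results),
#'   invisibly; `ok` is `FALSE` if any stage errored.
#' @export
run_full <- function(config, strict = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% tempfile("washbayes_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sc <- do.call(scenario_config,
                  c(config$simulate, list(seed = seed)))
    study <- generate_study(sc)
    access <- study$access
    covariates <- study$covariates
  } else {
    inp <- config$inputs
    access <- read_access_panel(inp$access, access_dialect(
      unit = inp$unit %||% "proportion", range = inp$range %||% "unit"))
    covariates <- read_covariates(inp$covariates, covariate_dialect())
  }
  covariates <- carry_democracy_2006_to_2000(covariates)
  access <- aggregate_basic_or_higher(access)

  mspec <- do.call(model_spec, c(list(seed = seed),
                                 config$model %||% list()))

  report <- list(seed = seed, outdir = outdir, stages = list(), ok = TRUE)
  results <- list()
  for (i in seq_along(config$analyses)) {
    an <- config$analyses[[i]]
    label <- paste0(an$stage, "_", i)
    yp <- as.integer(an$year_pair %||% c(2000L, 2020L))
    step <- .stage_try(label, switch(
      an$stage,
      screening = run_screening(access, covariates, an$service, an$quality,
                                an$area %||% "total", yp, spec = mspec),
      multivariable = run_multivariable(access, covariates, an$service,
                                        an$quality, an$area %||% "total", yp,
                                        gdp_variant = an$gdp_variant %||% "gdp_pc",
                                        spec = mspec),
      improvement = run_improvement(access, covariates, an$service,
                                    an$quality, yp, spec = mspec),
      descriptive = run_descriptive(access, .population_from(config)),
      stop("unknown stage: ", an$stage)), report)
    report <- step$report
    res <- step$result
    results[[label]] <- res
    if (inherits(res, "stage_error")) {
      report$ok <- FALSE
      if (strict) stop("stage '", label, "' failed: ", res$message)
      next
    }
    if (an$stage == "screening")
      write_result_table(res, file.path(outdir, paste0(label, ".csv")))
    if (an$stage == "multivariable") {
      write_result_table(res$summary, file.path(outdir, paste0(label, ".csv")))
      write_result_table(
        data.frame(variable = names(res$vif), vif = unname(res$vif)),
        file.path(outdir, paste0(label, "_vif.csv")))
    }
    if (an$stage == "improvement") {
      write_result_table(res$summary, file.path(outdir, paste0(label, ".csv")))
      write_improvement_table(res$table,
                              file.path(outdir, paste0(label, "_table.csv")))
    }
    if (an$stage == "descriptive")
      write_result_table(res, file.path(outdir, paste0(label, ".csv")))
  }

  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("washbayes")),
                   config = config)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  report$results <- results
  invisible(report)
}

.population_from <- function(config) {
  if (is.null(config$population))
    stop("descriptive stage requires a 'population' table or path")
  p <- config$population
  if (is.character(p))
    p <- read.table(p, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  as.data.frame(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
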