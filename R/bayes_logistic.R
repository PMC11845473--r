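#' Overflow-safe logistic function
#'
#' The inverse-logit link of the access-rate model: access rates live in
#' (0, 1) and follow diminishing marginal returns in the linear predictor.
#' Uses the stable two-branch form, safe for |eta| up to about 1e3.
#'
#' @param eta numeric vector of linear-predictor values.
#' @return values in (0, 1).
#' @examples
#' logistic(0)      # 0.5
#' logistic(2.33)   # ~0.911
#' @export
logistic <- function(eta) {
  out <- numeric(length(eta))
  pos <- !is.na(eta) & eta >= 0
  out[pos] <- 1 / (1 + exp(-eta[pos]))
  e <- exp(eta[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(eta)] <- NA_real_
  out
}

.theta_check <- function(theta) {
  stopifnot(is.list(theta), !is.null(theta$intercept))
  if (!is.null(theta$sigma) && theta$sigma <= 0)
    stop("sigma must be positive")
  theta
}

#' Model mean for one or more design rows
#'
#' logistic(intercept + sum C_i X_i + C_d X_d): the expected access rate at
#' normalized covariates `X` and year dummy `x_dummy` under coefficients
#' `theta`.
#'
#' @param X numeric vector (one row) or matrix of normalized covariates;
#'   column count must match `length(theta$coef)`.
#' @param x_dummy 0/1 scalar or vector (ignored when `theta$c_d` is `NULL`).
#' @param theta list with elements `intercept`, `coef` (named numeric,
#'   possibly empty), optional `c_d`, optional `sigma`.
#' @return expected proportions.
#' @export
model_mean <- function(X, x_dummy, theta) {
  .theta_check(theta)
  coef <- if (is.null(theta$coef)) numeric(0) else theta$coef
  if (is.null(dim(X))) X <- matrix(X, nrow = if (length(coef)) 1 else length(x_dummy))
  if (ncol(X) != length(coef))
    stop("X has ", ncol(X), " column(s) but theta has ", length(coef),
         " coefficient(s)")
  eta <- theta$intercept + if (length(coef)) drop(X %*% coef) else 0
  if (!is.null(theta$c_d)) eta <- eta + theta$c_d * x_dummy
  logistic(eta)
}

#' Model specification for the Bayesian access-rate regression
#'
#' Defaults follow the analysis protocol: independent normal(0, 50) priors
#' on the intercept and every coefficient, a half-normal(50) prior on sigma
#' (a normal(0, 50) truncated to the positive half-line), and MCMC with
#' 10,000 iterations per chain (2,000 of them warm-up, so 8,000 retained),
#' 4 chains. Convergence is declared when every split-chain R-hat is below
#' 1.10.
#'
#' @param factor_names ordered character vector of covariate names.
#' @param include_dummy include the 0/1 year-dummy term.
#' @param prior_sd prior standard deviation for all location parameters.
#' @param sigma_prior `"halfnormal"` or `"flat"` (improper uniform on
#'   (0, Inf)).
#' @param iterations total MCMC iterations per chain, including warm-up.
#' @param chains number of chains (>= 2, required for R-hat).
#' @param warmup warm-up (adaptation) iterations per chain.
#' @param thin keep every `thin`-th post-warm-up draw (1 = keep all).
#' @param seed integer seed governing the whole fit.
#' @param target_accept target Metropolis acceptance rate during adaptation.
#' @return a list of class `"model_spec"`.
#' @export
model_spec <- function(factor_names = character(0), include_dummy = TRUE,
                       prior_sd = 50, sigma_prior = c("halfnormal", "flat"),
                       iterations = 10000L, chains = 4L, warmup = 2000L,
                       thin = 1L, seed = 1L, target_accept = 0.3) {
  sigma_prior <- match.arg(sigma_prior)
  stopifnot(iterations > warmup, warmup >= 1, chains >= 2, prior_sd > 0,
            thin >= 1, (iterations - warmup) >= 4 * thin,
            target_accept > 0, target_accept < 1)
  structure(list(factor_names = factor_names,
                 include_dummy = isTRUE(include_dummy),
                 prior_sd = prior_sd, sigma_prior = sigma_prior,
                 iterations = as.integer(iterations),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 thin = as.integer(thin), seed = as.integer(seed),
                 target_accept = target_accept),
            class = "model_spec")
}

.design_matrix <- function(data, spec) {
  X <- data$X[, spec$factor_names, drop = FALSE]
  Z <- cbind(intercept = rep(1, length(data$y)), X)
  if (spec$include_dummy) {
    if (is.null(data$x_dummy))
      stop("model includes a year dummy but the dataset has none")
    Z <- cbind(Z, year_dummy = data$x_dummy)
  }
  Z
}

.param_names <- function(spec) {
  c("intercept", spec$factor_names,
    if (spec$include_dummy) "year_dummy", "sigma")
}

.theta_to_par <- function(theta, spec) {
  coef <- if (length(spec$factor_names)) theta$coef[spec$factor_names] else numeric(0)
  c(theta$intercept, coef, if (spec$include_dummy) theta$c_d, theta$sigma)
}

#' Joint log posterior density
#'
#' Sum of the Gaussian log likelihood of the observed rates around the
#' logistic model mean (standard deviation sigma) and the log prior
#' densities of all parameters. All normalizing constants are retained, so
#' the value equals an independent term-by-term density summation exactly.
#' `sigma <= 0` returns `-Inf`.
#'
#' @param theta coefficient list as in [model_mean()], with `sigma`.
#' @param data an [analysis_dataset()].
#' @param spec a [model_spec()].
#' @return scalar log posterior density.
#' @export
log_posterior <- function(theta, data, spec) {
  .theta_check(theta)
  par <- .theta_to_par(theta, spec)
  if (anyNA(par)) stop("theta lacks a parameter required by the model spec")
  Z <- .design_matrix(data, spec)
  .log_post_cpp(par, Z, data$y, spec$prior_sd,
                as.integer(spec$sigma_prior == "flat"))
}

#' Fit the Bayesian logistic-mean regression
#'
#' Samples the posterior of the access-rate model by adaptive random-walk
#' Metropolis (Haario-style covariance adaptation during warm-up, frozen
#' kernel afterwards). Chains start from jittered data-informed states and
#' share one seeded RNG stream, so the same seed reproduces the fit exactly.
#' Summaries (posterior mean, central 95% credible interval, split-chain
#' R-hat, significance = the 95% interval excludes 0) are computed from the
#' pooled post-warm-up draws. Non-convergence (any R-hat >= 1.10) yields a
#' warning and `converged = FALSE`, never an error.
#'
#' @param data an [analysis_dataset()].
#' @param spec a [model_spec()]; defaults to one derived from the dataset
#'   (all its factor columns, dummy iff the dataset has one).
#' @return object of class `"wash_fit"`: `draws` (list of per-chain matrices,
#'   one column per parameter), `summary` (see [fit_summary()]), `converged`,
#'   `spec`, `n_rows`, `n_countries_per_year`.
#' @export
fit_model <- function(data, spec = NULL) {
  stopifnot(inherits(data, "analysis_dataset"))
  if (is.null(spec))
    spec <- model_spec(factor_names = colnames(data$X),
                       include_dummy = !is.null(data$x_dummy))
  Z <- .design_matrix(data, spec)
  pn <- .param_names(spec)
  n <- length(data$y)
  d <- ncol(Z) + 1L
  flat <- as.integer(spec$sigma_prior == "flat")

  set.seed(spec$seed)
  lap <- .laplace_precondition(Z, data$y, spec$prior_sd, flat)
  base_init <- lap$mode
  jitter_sd <- pmax(diag(lap$chol %*% t(lap$chol))^0.5, 1e-8)

  chains <- vector("list", spec$chains)
  for (k in seq_len(spec$chains)) {
    repeat {  # jittered start; redraw on the rare non-positive sigma
      init <- base_init + rnorm(d, 0, jitter_sd)
      if (init[d] > 0) break
    }
    dr <- .run_chain_cpp(Z, data$y, spec$prior_sd, flat,
                         spec$iterations, spec$warmup, spec$thin, init,
                         lap$chol * (2.38 / sqrt(d)), spec$target_accept)
    colnames(dr) <- pn
    chains[[k]] <- dr
  }

  summ <- .summarize_chains(chains)
  converged <- all(summ$rhat < 1.10, na.rm = TRUE)
  if (!converged)
    warning("MCMC did not converge: max R-hat = ",
            format(max(summ$rhat), digits = 4))

  n_countries <- if (!is.null(data$country)) length(unique(data$country)) else n
  structure(list(draws = chains, summary = summ, converged = converged,
                 spec = spec, n_rows = n, n_countries = n_countries,
                 n_countries_per_year = data$n_countries_per_year),
            class = "wash_fit")
}

# Laplace approximation used only to precondition and initialize the
# sampler: posterior mode by quasi-Newton optimization and a covariance from
# the inverse Hessian at the mode. For prior-only (zero-row) data the mode
# of sigma sits on the boundary under the half-normal prior, so the prior's
# own scale is used instead. Any failure falls back to a diagonal guess; the
# warm-up adaptation then takes over.
.laplace_precondition <- function(Z, y, prior_sd, flat) {
  d <- ncol(Z) + 1L
  n <- length(y)
  mode <- rep(0, d)
  scales <- rep(0.1, d)
  if (n >= 2) {
    mode[1] <- qlogis(min(max(mean(y), 0.02), 0.98))
    mode[d] <- max(sd(y) / 2, 1e-3)
    scales[d] <- 0.25 * mode[d]
  } else {
    mode[d] <- prior_sd / 2
    scales <- rep(prior_sd, d)
    return(list(mode = mode, chol = diag(scales)))
  }
  neg_lp <- function(par) -.log_post_cpp(par, Z, y, prior_sd, flat)
  opt <- tryCatch(
    stats::optim(mode, neg_lp, method = "L-BFGS-B",
                 lower = c(rep(-Inf, d - 1L), 1e-8),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value)) {
    mode <- opt$par
    H <- tryCatch(stats::optimHess(mode, neg_lp), error = function(e) NULL)
    if (!is.null(H)) {
      Sig <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Sig)) {
        L <- tryCatch(t(chol(Sig)), error = function(e) NULL)
        if (!is.null(L)) return(list(mode = mode, chol = L))
      }
    }
  }
  list(mode = mode, chol = diag(scales))
}

.summarize_chains <- function(chains) {
  pooled <- do.call(rbind, chains)
  pn <- colnames(pooled)
  s <- data.frame(
    parameter = pn,
    mean = colMeans(pooled),
    cri_lower = apply(pooled, 2, quantile, probs = 0.025, names = FALSE),
    cri_upper = apply(pooled, 2, quantile, probs = 0.975, names = FALSE),
    rhat = vapply(pn, function(p)
      rhat(sapply(chains, function(ch) ch[, p])), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  s$significant <- s$cri_lower > 0 | s$cri_upper < 0
  s
}

#' Split-chain Gelman-Rubin statistic (R-hat)
#'
#' Each chain is split in half; with W the mean within-half-chain variance,
#' B/n the between-half-chain variance of the means, and n the half-chain
#' length, R-hat = sqrt((W (n - 1) / n + B / n) / W). Values near 1 indicate
#' the chains have mixed; the convergence rule used throughout the package
#' is R-hat < 1.10 for every parameter. If every half-chain is constant the
#' statistic is degenerate and returned as 1 with a warning.
#'
#' @param chains a numeric matrix (one column per chain) or list of equal
#'   length numeric vectors; at least 2 chains of at least 4 draws.
#' @return scalar R-hat.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2 || nrow(chains) < 4)
    stop("R-hat needs at least 2 chains of at least 4 draws")
  n2 <- nrow(chains) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j)
    cbind(chains[seq_len(n2), j],
          chains[seq.int(nrow(chains) - n2 + 1, nrow(chains)), j])))
  W <- mean(apply(halves, 2, var))
  if (W == 0) {
    warning("zero within-chain variance in every chain; R-hat degenerate")
    return(1.0)
  }
  B_over_n <- var(colMeans(halves))
  sqrt((W * (n2 - 1) / n2 + B_over_n) / W)
}

#' Summary table of a fit
#'
#' One row per parameter: posterior mean, central 95% credible interval
#' bounds, split-chain R-hat, significance flag (interval excludes 0) and
#' the number of countries entering the fit. Values are stored at full
#' precision; the print method displays 2 decimals, matching how such
#' tables are conventionally reported.
#'
#' @param fit a `"wash_fit"`.
#' @return data frame of class `"fit_summary"`.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "wash_fit"))
  s <- fit$summary
  s$n_countries <- fit$n_countries
  class(s) <- c("fit_summary", "data.frame")
  s
}

#' @export
summary.wash_fit <- function(object, ...) fit_summary(object)

#' @export
print.fit_summary <- function(x, ...) {
  d <- as.data.frame(x)
  for (col in c("mean", "cri_lower", "cri_upper")) d[[col]] <- round(d[[col]], 2)
  d$rhat <- round(d$rhat, 3)
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
print.wash_fit <- function(x, ...) {
  cat(sprintf("<wash_fit> %d chains x %d retained draws, %d rows%s\n",
              length(x$draws), nrow(x$draws[[1]]), x$n_rows,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(fit_summary(x))
  invisible(x)
}

#' Export posterior draws as delimited text
#'
#' One column per parameter, pooled across chains, for external diagnostics.
#'
#' @param fit a `"wash_fit"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  pooled <- as.data.frame(do.call(rbind, fit$draws))
  write.table(pooled, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
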