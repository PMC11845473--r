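test_that("logistic is stable, symmetric and matches direct evaluation", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(2.33), 1 / (1 + exp(-2.33)))
  eta <- c(-7.3, -0.1, 0.4, 3.2)
  expect_equal(logistic(eta) + logistic(-eta), rep(1, 4), tolerance = 1e-15)
  expect_equal(logistic(1000), 1)
  expect_equal(logistic(-1000), 0)
  expect_true(logistic(-1000) >= 0)
})

test_that("model_mean reduces correctly and validates lengths", {
  th <- list(intercept = 1.4, coef = c(a = 0, b = 0), c_d = 0, sigma = 0.1)
  expect_equal(model_mean(c(3, -2), 0, th), logistic(1.4))
  th0 <- list(intercept = 0, coef = c(a = 0, b = 0), c_d = 0)
  expect_equal(model_mean(c(5, 5), 1, th0), 0.5)
  # printed-coefficient style evaluation: intercept + dummy shift only
  th2 <- list(intercept = 2.33,
              coef = c(gdp = 1.07, urban = 0.37, democracy = 0.16),
              c_d = -0.18)
  expect_equal(model_mean(c(0, 0, 0), 1, th2), logistic(2.33 - 0.18))
  expect_error(model_mean(c(1, 2, 3), 0, th), "coefficient")
})

make_fixture_dataset <- function() {
  X <- matrix(c(-1.2, 0.3, 0.8, -0.4, 0.5,
                0.9, -1.1, 0.2, 0.7, -0.7,
                0.1, 0.4, -0.9, 1.3, -0.9), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  analysis_dataset(y = c(0.62, 0.48, 0.91, 0.33, 0.75), X = X,
                   x_dummy = c(0, 0, 1, 1, 1))
}

test_that("log posterior equals a term-by-term density summation", {
  ds <- make_fixture_dataset()
  spec <- model_spec(c("f1", "f2", "f3"), include_dummy = TRUE)
  th <- list(intercept = 0.4, coef = c(f1 = 0.9, f2 = -0.3, f3 = 0.1),
             c_d = -0.2, sigma = 0.07)

  # independent brute-force oracle: every density term computed separately
  oracle <- 0
  for (i in seq_along(ds$y)) {
    eta <- th$intercept + sum(ds$X[i, ] * th$coef) + th$c_d * ds$x_dummy[i]
    oracle <- oracle + dnorm(ds$y[i], plogis(eta), th$sigma, log = TRUE)
  }
  for (b in c(th$intercept, th$coef, th$c_d))
    oracle <- oracle + dnorm(b, 0, 50, log = TRUE)
  oracle <- oracle + dnorm(th$sigma, 0, 50, log = TRUE) + log(2)

  expect_equal(log_posterior(th, ds, spec), oracle, tolerance = 1e-10)

  # doubling the rows doubles the likelihood part exactly
  ds2 <- analysis_dataset(y = c(ds$y, ds$y), X = rbind(ds$X, ds$X),
                          x_dummy = c(ds$x_dummy, ds$x_dummy))
  prior_part <- log_posterior(th, analysis_dataset(
    y = numeric(0), X = ds$X[0, , drop = FALSE], x_dummy = numeric(0)), spec)
  lik1 <- log_posterior(th, ds, spec) - prior_part
  lik2 <- log_posterior(th, ds2, spec) - prior_part
  expect_equal(lik2, 2 * lik1, tolerance = 1e-10)

  # sigma -> 0+ sends the posterior density to -Inf for misfitting data
  th_small <- th
  th_small$sigma <- 1e-12
  expect_lt(log_posterior(th_small, ds, spec), -1e6)
  th_zero <- th
  th_zero$sigma <- 0
  expect_error(log_posterior(th_zero, ds, spec), "sigma")
})

test_that("flat sigma prior drops only the sigma prior term", {
  ds <- make_fixture_dataset()
  th <- list(intercept = 0.1, coef = c(f1 = 0, f2 = 0, f3 = 0), c_d = 0,
             sigma = 0.2)
  s1 <- model_spec(c("f1", "f2", "f3"))
  s2 <- model_spec(c("f1", "f2", "f3"), sigma_prior = "flat")
  expect_equal(log_posterior(th, ds, s1) - log_posterior(th, ds, s2),
               dnorm(0.2, 0, 50, log = TRUE) + log(2), tolerance = 1e-12)
})

test_that("split-chain R-hat matches the closed-form oracle", {
  # deterministic fixture: same nonconstant sequence in both chains
  x <- c(0.1, 0.2, 0.4, 0.3, 0.7, 0.9, 0.6, 0.8)
  chains <- cbind(x, x)
  # direct formula: split each chain in half, W, B/n over the 4 half-chains
  halves <- cbind(x[1:4], x[5:8], x[1:4], x[5:8])
  W <- mean(apply(halves, 2, var))
  B_over_n <- var(colMeans(halves))
  oracle <- sqrt((W * 3 / 4 + B_over_n) / W)
  expect_equal(rhat(chains), oracle, tolerance = 1e-6)
  expect_gte(rhat(chains), 1)

  # same-distribution chains converge to 1
  set.seed(11)
  expect_lt(abs(rhat(cbind(rnorm(10000), rnorm(10000))) - 1), 0.05)

  # far-separated chains are flagged
  expect_gt(rhat(cbind(rnorm(100), rnorm(100, 100))), 1.10)

  # degenerate constant chains
  expect_warning(r <- rhat(cbind(rep(1, 8), rep(1, 8))), "degenerate")
  expect_equal(r, 1.0)
  expect_error(rhat(matrix(1:4, ncol = 1)), "2 chains")
})

test_that("posterior summaries: quantile oracle, significance, degenerate draws", {
  set.seed(3)
  z <- matrix(rnorm(10000), ncol = 2)
  s <- washbayes:::.summarize_chains(list(structure(z[, 1, drop = FALSE],
                                                    dimnames = list(NULL, "p")),
                                          structure(z[, 2, drop = FALSE],
                                                    dimnames = list(NULL, "p"))))
  expect_lt(abs(s$cri_lower + 1.96), 0.06)
  expect_lt(abs(s$cri_upper - 1.96), 0.06)
  expect_false(s$significant)  # symmetric draws around 0

  cnst <- matrix(0.5, 50, 1, dimnames = list(NULL, "p"))
  s2 <- suppressWarnings(
    washbayes:::.summarize_chains(list(cnst, cnst)))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$cri_lower, 0.5)
  expect_equal(s2$cri_upper, 0.5)
  expect_true(s2$significant)
})

test_that("fits are reproducible given a seed", {
  ds <- make_fixture_dataset()
  ds2 <- analysis_dataset(y = rep(ds$y, 4), X = ds$X[rep(1:5, 4), ],
                          x_dummy = rep(ds$x_dummy, 4))
  sp <- model_spec(c("f1", "f2", "f3"), iterations = 600, warmup = 200,
                   chains = 2, seed = 21)
  f1 <- quiet(fit_model(ds2, sp))
  f2 <- quiet(fit_model(ds2, sp))
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)
})

test_that("near-noiseless data pin the intercept (intercept-only model)", {
  set.seed(2)
  n <- 60
  y <- logistic(1.0) + rnorm(n, 0, 1e-4)
  ds <- analysis_dataset(y = y, X = matrix(numeric(0), n, 0), x_dummy = NULL)
  sp <- model_spec(character(0), include_dummy = FALSE,
                   iterations = 3000, warmup = 1000, chains = 2, seed = 4)
  fit <- quiet(fit_model(ds, sp))
  expect_lt(abs(fit$summary$mean[fit$summary$parameter == "intercept"] - 1.0),
            0.01)
})

test_that("with no data the posterior reproduces the prior scale", {
  ds <- analysis_dataset(y = numeric(0),
                         X = matrix(numeric(0), 0, 1,
                                    dimnames = list(NULL, "f")),
                         x_dummy = NULL)
  sp <- model_spec("f", include_dummy = FALSE, seed = 8)  # 4 x 8000 draws
  fit <- quiet(fit_model(ds, sp))
  pooled <- do.call(rbind, fit$draws)
  expect_gt(nrow(pooled), 10000)
  expect_lt(abs(sd(pooled[, "intercept"]) - 50) / 50, 0.10)
  expect_lt(abs(sd(pooled[, "f"]) - 50) / 50, 0.10)
  # half-normal(50) sd = 50 * sqrt(1 - 2/pi)
  expect_lt(abs(sd(pooled[, "sigma"]) - 50 * sqrt(1 - 2 / pi)) /
              (50 * sqrt(1 - 2 / pi)), 0.15)
})

test_that("model mean is monotone in a positive-coefficient covariate", {
  th <- list(intercept = 0.3, coef = c(a = 0.8, b = -0.2), c_d = -0.5)
  grid <- seq(-4, 4, length.out = 41)
  for (b in c(-1, 0, 2)) {
    m <- model_mean(cbind(a = grid, b = b), 1, th)
    expect_true(all(diff(m) >= 0))
  }
})
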