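sim_gp_data <- function(n, beta = c(10, 3), sigma2 = 4, tau2 = 1,
                        phi = 0.01, extent = 1000, seed = 1) {
  set.seed(seed)
  coords <- matrix(runif(2 * n, 0, extent), n, 2)
  X <- cbind(intercept = 1, metric = rnorm(n))
  D <- as.matrix(dist(coords))
  R <- sigma2 * exp(-phi * D)
  w <- drop(crossprod(chol(R + diag(1e-8, n)), rnorm(n)))
  y <- drop(X %*% beta) + w + rnorm(n, 0, sqrt(tau2))
  list(y = y, X = X, coords = coords, w = w,
       truth = c(beta, sigma2 = sigma2, tau2 = tau2, phi = phi))
}

test_that("with negligible spatial variance the posterior matches OLS", {
  set.seed(20)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(5, 2)) + rnorm(n, 0, 1)
  coords <- matrix(runif(2 * n, 0, 1000), n, 2)
  fit <- fit_spatial_regression(y, X, coords,
                                mcmc = list(n_iter = 3000, burn_in = 1500,
                                            thin = 3),
                                seed = 8)
  ols <- coef(lm(y ~ X[, 2]))
  post <- colMeans(fit$samples$beta)
  mcse <- apply(fit$samples$beta, 2, sd)
  expect_lt(abs(post[1] - ols[1]), 3 * mcse[1] + 0.05)
  expect_lt(abs(post[2] - ols[2]), 3 * mcse[2] + 0.05)
})

test_that("seeded MCMC is reproducible draw for draw", {
  d <- sim_gp_data(60, seed = 2)
  mc <- list(n_iter = 800, burn_in = 400, thin = 2)
  f1 <- fit_spatial_regression(d$y, d$X, d$coords, mcmc = mc, seed = 99)
  f2 <- fit_spatial_regression(d$y, d$X, d$coords, mcmc = mc, seed = 99)
  expect_identical(f1$samples, f2$samples)
})

test_that("duplicate coordinates are rejected", {
  d <- sim_gp_data(30, seed = 3)
  d$coords[2, ] <- d$coords[1, ]
  expect_error(fit_spatial_regression(d$y, d$X, d$coords), "duplicate")
})

test_that("exponential correlation matrices factor for distinct coordinates", {
  for (seed in 1:5) {
    set.seed(seed)
    coords <- matrix(runif(80), 40, 2) * 500
    R <- exp(-0.02 * as.matrix(dist(coords)))
    expect_silent(chol(R))   # SPD iff the factorization succeeds
  }
})

test_that("prediction interpolates the data as tau2 -> 0", {
  d <- sim_gp_data(80, sigma2 = 25, tau2 = 0.01, phi = 0.005, seed = 4)
  # pin tau2 near zero through a tight inverse-gamma prior
  fit <- fit_spatial_regression(d$y, d$X, d$coords,
                                priors = list(tau2 = c(1000, 0.01 * 999)),
                                mcmc = list(n_iter = 3000, burn_in = 1500,
                                            thin = 3),
                                seed = 5)
  pred <- predict_posterior(fit, d$X, d$coords, n_draws = 200, seed = 6)
  rmse <- sqrt(mean((pred$mean - d$y)^2))
  expect_lt(rmse, 0.1 * sd(d$y))
  expect_true(all(pred$lower <= pred$mean & pred$mean <= pred$upper))
})

test_that("far-field predictions collapse to the regression surface", {
  d <- sim_gp_data(100, beta = c(10, 3), sigma2 = 4, tau2 = 1, phi = 0.01,
                   seed = 7)
  fit <- fit_spatial_regression(d$y, d$X, d$coords,
                                mcmc = list(n_iter = 4000, burn_in = 2000,
                                            thin = 4),
                                seed = 9)
  # phi * d >> 1: 60+ correlation lengths away from every observation
  X_far <- cbind(intercept = 1, metric = c(-1, 0, 2))
  coords_far <- cbind(c(9e5, 9.1e5, 9.2e5), c(9e5, 9.1e5, 9.2e5))
  pred <- predict_posterior(fit, X_far, coords_far, n_draws = 500, seed = 10)
  eb <- colMeans(fit$samples$beta)
  closed_mean <- drop(X_far %*% eb)
  closed_var <- mean(fit$samples$sigma2) + mean(fit$samples$tau2)
  expect_equal(pred$mean, closed_mean, tolerance = 0.15)
  emp_var <- ((pred$upper - pred$lower) / (2 * qnorm(0.975)))^2
  expect_equal(mean(emp_var), closed_var, tolerance = 0.3)
})

test_that("predictive intervals widen as the tau2 prior shifts upward", {
  d <- sim_gp_data(60, seed = 11)
  v <- var(d$y)
  mc <- list(n_iter = 2000, burn_in = 1000, thin = 2)
  Xn <- cbind(1, c(-0.5, 0.5)); cn <- cbind(c(200, 600), c(300, 700))
  w_low <- w_high <- NA
  fit_lo <- fit_spatial_regression(d$y, d$X, d$coords,
                                   priors = list(tau2 = c(2, v / 10)),
                                   mcmc = mc, seed = 12)
  fit_hi <- fit_spatial_regression(d$y, d$X, d$coords,
                                   priors = list(tau2 = c(2, 5 * v)),
                                   mcmc = mc, seed = 12)
  p_lo <- predict_posterior(fit_lo, Xn, cn, n_draws = 300, seed = 13)
  p_hi <- predict_posterior(fit_hi, Xn, cn, n_draws = 300, seed = 13)
  expect_gt(mean(p_hi$upper - p_hi$lower), mean(p_lo$upper - p_lo$lower))
})

test_that("ensemble baseline learns signal and rejects permuted labels", {
  set.seed(30)
  n <- 400
  X <- data.frame(m1 = runif(n, 0, 10), m2 = rnorm(n))
  y <- 3 * X$m1^1.5
  rf <- fit_ensemble_baseline(y, X, n_trees = 500, seed = 1)
  expect_equal(rf$n_trees, 500)
  expect_gt(rf$oob_r2, 0.9)
  rf_null <- fit_ensemble_baseline(sample(y), X, n_trees = 300, seed = 2)
  expect_lt(rf_null$oob_r2, 0.2)
  pred <- fit_ensemble_baseline(y, X, n_trees = 200, X_new = X[1:5, ],
                                seed = 3)$predictions
  expect_length(pred, 5)
})

test_that("the empirical semivariogram behaves as theory dictates", {
  set.seed(40)
  coords <- matrix(runif(400, 0, 1000), 200, 2)
  # constant residuals: zero semivariance everywhere
  vg0 <- variogram_check(rep(3.3, 200), coords, lag_bins = 8)
  expect_true(all(vg0$gamma[vg0$n_pairs > 0] == 0))

  # independent noise: flat variogram at the noise variance
  v <- 4
  vg1 <- variogram_check(rnorm(200, 0, sqrt(v)), coords, lag_bins = 6)
  ok <- vg1$n_pairs > 100
  expect_equal(mean(vg1$gamma[ok]), v, tolerance = 0.2)

  # GP residuals track sigma2 * (1 - exp(-phi d))
  sigma2 <- 9; phi <- 0.008
  R <- sigma2 * exp(-phi * as.matrix(dist(coords)))
  z <- drop(crossprod(chol(R + diag(1e-8, 200)), rnorm(200)))
  vg2 <- variogram_check(z, coords, lag_bins = 8)
  ok <- vg2$n_pairs > 200
  theory <- sigma2 * (1 - exp(-phi * vg2$lag_mid[ok]))
  expect_lt(mean(abs(vg2$gamma[ok] - theory) / theory), 0.35)

  # empty bins are missing, not zero
  vg3 <- variogram_check(rnorm(40), coords[1:40, ],
                         lag_bins = c(0, 1, 2, 500))
  expect_true(is.na(vg3$gamma[1]))
  expect_error(variogram_check(rnorm(10), coords[1:10, ]), "at least 30")
})
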