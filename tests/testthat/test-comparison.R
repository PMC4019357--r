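test_that("plot extraction averages the four subplot pixels", {
  g <- grid_spec(2, 2, 30)
  vals <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)
  r <- grid_raster(vals, g)
  uniform <- grid_raster(matrix(7, 2, 2), g)

  # one subplot center in each pixel -> mean of the four values
  cl <- plot_cluster(1, rbind(c(15, 45), c(45, 45), c(15, 15), c(45, 15)),
                     "FIA")
  expect_equal(extract_plot_prediction(r, cl), mean(c(10, 20, 30, 40)))
  expect_equal(extract_plot_prediction(uniform, cl), 7)

  # NFI: single center pixel
  nfi <- plot_cluster(2, cbind(45, 15), "NFI")
  expect_equal(extract_plot_prediction(r, nfi), 40)

  # center exactly on the internal boundary: deterministic half-open rule
  on_edge <- plot_cluster(3, rbind(c(30, 30), c(15, 45), c(45, 45), c(15, 15)),
                          "FIA")
  # (30, 30) belongs to row 2, col 2 -> value 40
  expect_equal(extract_plot_prediction(r, on_edge),
               mean(c(40, 10, 20, 30)))

  # no-data pixel raises the typed condition; network extraction excludes it
  vals_na <- vals; vals_na[1, 1] <- NA
  r_na <- grid_raster(vals_na, g)
  expect_error(extract_plot_prediction(r_na, cl), class = "forestAGB_missing_data")
  suppressMessages(
    out <- extract_network_predictions(r_na, list(cl, nfi))
  )
  expect_equal(as.numeric(out), 40)
  expect_equal(attr(out, "excluded"), "1")
})

test_that("agreement regression matches closed-form OLS", {
  field <- c(12, 40, 75, 110, 160, 210)
  ident <- agreement_regression(field, field)
  expect_equal(ident$slope, 1)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$rmse, 0)

  doubled <- agreement_regression(field, 2 * field)
  expect_equal(doubled$slope, 2)
  expect_equal(doubled$r_squared, 1)

  shifted <- agreement_regression(field, field + 25)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$rmse, 25)

  set.seed(50)
  mapped <- 0.8 * field + rnorm(6, 0, 5)
  got <- agreement_regression(field, mapped)
  sxx <- sum((field - mean(field))^2)
  slope_hand <- sum((field - mean(field)) * (mapped - mean(mapped))) / sxx
  expect_equal(got$slope, slope_hand)
  expect_equal(got$r_squared, cor(field, mapped)^2)
  expect_equal(got$rmse, sqrt(mean((mapped - field)^2)))
  expect_equal(agreement_regression(field, mapped,
                                    rmse_type = "residual")$rmse,
               sqrt(mean(residuals(lm(mapped ~ field))^2)))

  expect_error(agreement_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_error(agreement_regression(rep(5, 6), field), "zero variance")
})

test_that("the slope recovers 1 and RMSE the noise SD on truth + noise maps", {
  set.seed(51)
  field <- rgamma(500, 2, scale = 60)
  mapped <- field + rnorm(500, 0, 15)
  got <- agreement_regression(field, mapped)
  expect_equal(got$slope, 1, tolerance = 0.05)
  expect_equal(got$rmse, 15, tolerance = 0.1)
})

test_that("KS statistic equals the exhaustive oracle, including ties", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(10, 11, 12)), 1)
  set.seed(60)
  for (rep in 1:25) {
    na <- sample(1:10, 1); nb <- sample(1:10, 1)
    a <- sample(0:8, na, replace = TRUE) + sample(c(0, 0.5), na, TRUE)
    b <- sample(0:8, nb, replace = TRUE)
    expect_equal(ks_statistic(a, b), oracle_ks(a, b))
    # symmetry and invariance under a common strictly monotone transform
    expect_equal(ks_statistic(a, b), ks_statistic(b, a))
    expect_equal(ks_statistic(exp(a / 3), exp(b / 3)), ks_statistic(a, b))
  }
  # cross-check against the reference implementation on tie-free samples
  a <- rnorm(40); b <- rnorm(50, 0.4)
  expect_equal(ks_statistic(a, b),
               unname(suppressWarnings(ks.test(a, b)$statistic)))
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("interval overlap equals a hand count", {
  same <- data.frame(lo95 = c(1, 5, 9), hi95 = c(2, 6, 10))
  expect_equal(ci_overlap_fraction(same, same), 1)
  disjoint <- data.frame(lo95 = c(20, 30, 40), hi95 = c(21, 31, 41))
  expect_equal(ci_overlap_fraction(same, disjoint), 0)

  a <- data.frame(lo95 = c(0, 0, 5, 5, 2, 10, -3, 7, 1, 4),
                  hi95 = c(1, 4, 9, 6, 8, 20, -1, 7, 3, 4))
  b <- data.frame(lo95 = c(1, 5, 0, 7, 9, 15, 0, 7, 10, 4.5),
                  hi95 = c(2, 6, 4, 8, 12, 18, 2, 9, 11, 5))
  # pair-by-pair hand count: touching endpoints (pairs 1 and 8) overlap
  hand <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(ci_overlap_fraction(a, b), mean(hand))

  expect_error(ci_overlap_fraction(data.frame(lo95 = 2, hi95 = 1), a[1, ]),
               "malformed")
  expect_error(ci_overlap_fraction(a[1:3, ], b), "paired")
})

test_that("CDF tables expose rank/n cumulative proportions", {
  single <- cdf_table(42)
  expect_equal(single, data.frame(value = 42, cum_prop = 1))

  tab <- cdf_table(c(1, 2, 3, 4))
  # CDF evaluated just below 3 (e.g. at 2.5) is 0.5
  expect_equal(tab$cum_prop[tab$value == 2], 0.5)

  set.seed(70)
  x <- rnorm(101)
  tab <- cdf_table(x)
  brute <- vapply(tab$value, function(v) mean(x <= v), numeric(1))
  expect_equal(tab$cum_prop, brute)
  # the sample median is readable from the table (odd n: an observed value)
  expect_equal(min(tab$value[tab$cum_prop >= 0.5]), median(x))
  expect_error(cdf_table(numeric(0)), "non-empty")
})

test_that("excluding nonforest pairs changes the statistics deterministically", {
  g <- grid_spec(6, 6, 30)
  set.seed(80)
  r <- grid_raster(matrix(runif(36, 20, 220), 6, 6), g)
  net <- generate_plot_network(g, 9, "FIA", seed = 81)
  field <- c(0, 0, 130, 95, 0, 180, 60, 20, 210)
  names(field) <- as.character(1:9)
  all_pairs <- compare_plots_map(field, r, net)
  forest_only <- compare_plots_map(field, r, net, exclude_nonforest = TRUE)
  expect_equal(all_pairs$n_pairs, 9)
  expect_equal(forest_only$n_pairs, 6)
  redo <- agreement_regression(all_pairs$field[all_pairs$field > 0],
                               all_pairs$mapped[all_pairs$field > 0])
  expect_equal(forest_only$r_squared, redo$r_squared)
  expect_equal(forest_only$slope, redo$slope)
})
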