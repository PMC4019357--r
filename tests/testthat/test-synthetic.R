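test_that("surface generator honors its degenerate and clipping contracts", {
  g <- grid_spec(12, 12, 30)
  all_nf <- generate_biomass_surface(g, nonforest_fraction = 1, seed = 3,
                                     scattered_trees = FALSE)
  expect_true(all(all_nf$biomass == 0))
  expect_true(all(all_nf$condition == "nonforest"))

  for (seed in 1:3) {
    s <- generate_biomass_surface(g, spatial_params = list(sill = 3000,
                                                           decay = 0.02,
                                                           mean = 10),
                                  nonforest_fraction = 0.3, seed = seed)
    expect_true(min(s$biomass) >= 0)
    expect_true(all(s$condition %in% c("forest", "nonforest")))
  }
  expect_error(generate_biomass_surface(g, nonforest_fraction = 1.2),
               "nonforest_fraction")
  expect_error(generate_biomass_surface(g, spatial_params = list(sill = -1,
                                                                 decay = 0.1,
                                                                 mean = 0)),
               "positive")
})

test_that("surface spatial structure matches the exponential variogram", {
  # brute-force semivariogram over all pixel pairs vs sill*(1 - exp(-decay*d))
  g <- grid_spec(50, 50, 30)
  sill <- 400; decay <- 0.05
  s <- generate_biomass_surface(g, spatial_params = list(sill = sill,
                                                         decay = decay,
                                                         mean = 150),
                                nonforest_fraction = 0, seed = 11)
  pc <- pixel_centers(g)
  z <- s$biomass[cbind(pc$row, pc$col)]
  D <- as.matrix(dist(pc[, c("x", "y")]))
  for (lag in c(30, 60, 90)) {
    pair <- which(abs(D - lag) < 0.5 & upper.tri(D), arr.ind = TRUE)
    gamma_emp <- mean(0.5 * (z[pair[, 1]] - z[pair[, 2]])^2)
    gamma_theory <- sill * (1 - exp(-decay * lag))
    expect_lt(abs(gamma_emp - gamma_theory) / gamma_theory, 0.25)
  }
})

test_that("scattered-tree surfaces hit the configured nonforest biomass share", {
  g <- grid_spec(30, 30, 30)
  for (share in c(0.1, 0.25)) {
    s <- generate_biomass_surface(g, nonforest_fraction = 0.4, seed = 7,
                                  scattered_trees = TRUE,
                                  nonforest_biomass_share = share)
    nf <- s$condition == "nonforest"
    expect_equal(sum(s$biomass[nf]) / sum(s$biomass), share, tolerance = 1e-6)
  }
})

test_that("plot clusters have the stated geometry", {
  g <- grid_spec(20, 20, 30)
  net <- generate_plot_network(g, 1, "FIA", seed = 2)
  cl <- net[[1]]
  expect_equal(nrow(cl$centers), 4L)
  expect_equal(cl$subplot_area, 168)
  d_center <- sqrt(rowSums((cl$centers[-1, ] -
                              matrix(cl$centers[1, ], 3, 2, TRUE))^2))
  expect_equal(d_center, rep(7, 3))
  # satellites at 120-degree azimuths are 7*sqrt(3) apart
  d_sat <- dist(cl$centers[-1, ])
  expect_equal(as.numeric(d_sat), rep(7 * sqrt(3), 3), tolerance = 1e-9)

  nfi <- generate_plot_network(g, 2, "NFI", seed = 2)
  expect_equal(nrow(nfi[[1]]$centers), 1L)
  expect_equal(nfi[[1]]$subplot_area, 400)

  ext <- c(0, 600)
  for (cl in generate_plot_network(g, 25, "FIA", seed = 9)) {
    expect_true(all(cl$centers >= ext[1] & cl$centers <= ext[2]))
  }
  expect_error(generate_plot_network(g, 1e6), "exceeds")
})

test_that("systematic placement approximates the ideal lattice spacing", {
  g <- grid_spec(100, 100, 30)
  net <- generate_plot_network(g, 100, "FIA", seed = 4)
  xy <- t(vapply(net, function(cl) cl$centers[1, ], numeric(2)))
  D <- as.matrix(dist(xy)); diag(D) <- Inf
  nn <- apply(D, 1, min)
  ideal <- sqrt(3000 * 3000 / 100)
  expect_true(all(abs(nn - ideal) / ideal <= 0.10))
})

test_that("FIA_LIKE placement lands on forest pixels only", {
  g <- grid_spec(20, 20, 30)
  s <- generate_biomass_surface(g, nonforest_fraction = 0.5, seed = 21)
  net <- generate_plot_network(g, 15, "FIA_LIKE", seed = 3, surface = s)
  for (cl in net) {
    px <- locate_pixel(g, cl$centers[1, 1], cl$centers[1, 2])
    expect_equal(s$condition[px$row, px$col], "forest")
  }
  expect_error(generate_plot_network(g, 3, "FIA_LIKE", seed = 1), "surface")
})

test_that("tree lists scale with local biomass and follow the Weibull", {
  s0 <- flat_surface(0)
  cl <- plot_cluster(1, rbind(c(100, 100), c(100, 107),
                              c(106.06, 96.5), c(93.94, 96.5)), "FIA")
  empty <- generate_tree_list(cl, s0, seed = 1)
  expect_equal(nrow(empty), 0L)

  # closed-form Weibull mean: scale * gamma(1 + 1/shape)
  s_dense <- flat_surface(300, n = 20)
  net <- generate_plot_network(s_dense$grid, 40, "FIA", seed = 6)
  trees <- do.call(rbind, lapply(net, function(cl) {
    generate_tree_list(cl, s_dense, stand_params(2, 20), seed = cl$plot_id)
  }))
  expect_gt(nrow(trees), 2000)
  expect_equal(mean(trees$dbh_cm), 20 * gamma(1.5), tolerance = 0.03)

  # determinism under a fixed seed
  t2 <- generate_tree_list(net[[1]], s_dense, stand_params(2, 20), seed = 1)
  t3 <- generate_tree_list(net[[1]], s_dense, stand_params(2, 20), seed = 1)
  expect_identical(t2, t3)
})

test_that("plot-summed true biomass tracks the underlying surface", {
  g <- grid_spec(30, 30, 30)
  s <- generate_biomass_surface(g, seed = 14)
  net <- generate_plot_network(g, 220, "FIA", seed = 8)
  sums <- vapply(net, function(cl) {
    sum(generate_tree_list(cl, s, seed = cl$plot_id)$true_biomass_kg)
  }, numeric(1))
  surf <- vapply(net, function(cl) {
    px <- locate_pixel(g, cl$centers[, 1], cl$centers[, 2])
    mean(s$biomass[cbind(px$row, px$col)])
  }, numeric(1))
  expect_gt(cor(sums, surf, method = "spearman"), 0.7)
})

test_that("canopy metrics are monotone in biomass and calibratable", {
  s <- generate_biomass_surface(grid_spec(25, 25, 30), seed = 5)
  noiseless <- generate_lidar_metrics(s, list(exponent = 0.5, noise_sd = 0),
                                      n_metrics = 2, seed = 1)
  expect_equal(cor(as.vector(noiseless[[1]]$values), as.vector(s$biomass),
                   method = "spearman"), 1)
  m1 <- generate_lidar_metrics(s, n_metrics = 3, seed = 9)
  m2 <- generate_lidar_metrics(s, n_metrics = 3, seed = 9)
  expect_identical(m1[[3]]$values, m2[[3]]$values)

  cal <- generate_lidar_metrics(s, n_metrics = 1, seed = 2, target_r2 = 0.67)
  refit <- summary(lm(as.vector(s$biomass) ~ as.vector(cal[[1]]$values)))
  expect_equal(refit$r.squared, 0.67, tolerance = 0.05)
  expect_error(generate_lidar_metrics(s, list(exponent = 1, noise_sd = -1)),
               "noise_sd")
})

test_that("inventory protocols censor exactly by condition", {
  forest <- toy_trees(6, condition = "forest")
  expect_identical(apply_inventory_protocol(forest, "FIA"), forest)

  nonforest <- toy_trees(5, condition = "nonforest")
  expect_equal(nrow(apply_inventory_protocol(nonforest, "FIA")), 0L)
  expect_equal(plot_biomass_density(apply_inventory_protocol(nonforest, "FIA"),
                                    670, registry = toy_registry()), 0)

  set.seed(31)
  mixed <- toy_trees(40, condition = sample(c("forest", "nonforest"), 40, TRUE))
  kept <- apply_inventory_protocol(mixed, "FIA")
  expect_identical(kept, mixed[mixed$condition != "nonforest", ])

  nfi <- apply_inventory_protocol(mixed, "NFI")
  expect_true(all(nfi$subplot_id == 1L))
  expect_identical(apply_inventory_protocol(mixed, "FIA_LIKE"), mixed)
  expect_error(apply_inventory_protocol(mixed, "PLOTLESS"))
})

test_that("censoring is monotone: FIA plot biomass never exceeds all-tree biomass", {
  g <- grid_spec(20, 20, 30)
  s <- generate_biomass_surface(g, seed = 17)
  net <- generate_plot_network(g, 30, "FIA", seed = 17)
  reg <- default_equation_registry()
  for (cl in net) {
    trees <- generate_tree_list(cl, s, seed = cl$plot_id, registry = reg)
    area <- cluster_sampled_area(cl)
    d_all <- plot_biomass_density(trees, area, registry = reg)
    d_fia <- plot_biomass_density(apply_inventory_protocol(trees, "FIA"),
                                  area, registry = reg)
    expect_lte(d_fia, d_all)
  }
})
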