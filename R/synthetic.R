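#' Simulate a true biomass surface with exponential spatial covariance
#'
#' Draws a Gaussian random field on the pixel centers with covariance
#' `sill * exp(-decay * d)`, shifts it by `mean`, and clips at zero; then
#' carves contiguous rectangular nonforest blocks covering approximately
#' `nonforest_fraction` of the landscape. With `scattered_trees = TRUE`
#' (fragmented canopies: yards, rights-of-way, field edges), nonforest
#' pixels retain tree biomass, rescaled so that the nonforest share of total
#' landscape biomass equals `nonforest_biomass_share`; with the flag off,
#' nonforest pixels are bare (biomass 0).
#'
#' Defaults describe a mid-Atlantic urbanizing county: mean 70 Mg/ha,
#' pixel-scale SD 50 Mg/ha, spatial correlation with an effective range of
#' about 300 m, 40% of the land in nonforest condition carrying 25% of the
#' biomass.
#'
#' @param grid a [grid_spec()].
#' @param spatial_params list with `sill` (variance, (Mg/ha)^2), `decay`
#'   (1/m; effective range about 3/decay) and `mean` (Mg/ha).
#' @param nonforest_fraction areal fraction of nonforest pixels, in [0, 1].
#' @param seed integer RNG seed.
#' @param scattered_trees keep (rescaled) tree biomass on nonforest pixels.
#' @param nonforest_biomass_share target share of total biomass on nonforest
#'   pixels when `scattered_trees` is on.
#' @return object of class `true_surface`: list with `grid`, `biomass`
#'   (matrix, Mg/ha) and `condition` (character matrix).
#' @export
generate_biomass_surface <- function(grid,
                                     spatial_params = list(sill = 2500,
                                                           decay = 0.01,
                                                           mean = 70),
                                     nonforest_fraction = 0.4,
                                     seed = 1,
                                     scattered_trees = TRUE,
                                     nonforest_biomass_share = 0.25) {
  stopifnot(inherits(grid, "grid_spec"))
  sp <- spatial_params
  if (is.null(sp$sill) || is.null(sp$decay) || sp$sill <= 0 || sp$decay <= 0) {
    stop("sill and decay must be positive", call. = FALSE)
  }
  if (nonforest_fraction < 0 || nonforest_fraction > 1) {
    stop("nonforest_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (scattered_trees &&
      (nonforest_biomass_share < 0 || nonforest_biomass_share >= 1)) {
    stop("nonforest_biomass_share must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  centers <- pixel_centers(grid)
  n <- nrow(centers)
  d <- as.matrix(stats::dist(centers[, c("x", "y")]))
  C <- sp$sill * exp(-sp$decay * d)
  L <- chol(C + diag(1e-8 * sp$sill, n))
  z <- (sp$mean %||% 0) + drop(crossprod(L, stats::rnorm(n)))
  biomass <- matrix(0, grid$n_rows, grid$n_cols)
  biomass[cbind(centers$row, centers$col)] <- pmax(z, 0)

  condition <- matrix("forest", grid$n_rows, grid$n_cols)
  target <- round(nonforest_fraction * n)
  guard <- 0L
  while (sum(condition == "nonforest") < target && guard < 10000L) {
    guard <- guard + 1L
    h <- sample.int(max(1L, grid$n_rows %/% 4), 1L)
    w <- sample.int(max(1L, grid$n_cols %/% 4), 1L)
    r0 <- sample.int(grid$n_rows - h + 1L, 1L)
    c0 <- sample.int(grid$n_cols - w + 1L, 1L)
    condition[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- "nonforest"
  }
  nf <- condition == "nonforest"
  if (any(nf)) {
    if (!scattered_trees || nonforest_biomass_share == 0) {
      biomass[nf] <- 0
    } else {
      # fragmented canopy: thin the carved pixels, then rescale so the
      # nonforest share of total biomass hits the configured value exactly
      biomass[nf] <- biomass[nf] * 0.5
      b_nf <- sum(biomass[nf]); b_f <- sum(biomass[!nf])
      s <- nonforest_biomass_share
      if (b_nf > 0 && b_f > 0) {
        biomass[nf] <- biomass[nf] * (s * b_f) / ((1 - s) * b_nf)
      }
    }
  }
  structure(list(grid = grid, biomass = biomass, condition = condition,
                 params = list(spatial = sp,
                               nonforest_fraction = nonforest_fraction,
                               scattered_trees = scattered_trees,
                               nonforest_biomass_share = nonforest_biomass_share,
                               seed = seed)),
            class = "true_surface")
}

#' @export
print.true_surface <- function(x, ...) {
  nf <- mean(x$condition == "nonforest")
  cat(sprintf("<true_surface> %d x %d; biomass %.1f-%.1f Mg/ha (mean %.1f); %.0f%% nonforest\n",
              x$grid$n_rows, x$grid$n_cols, min(x$biomass), max(x$biomass),
              mean(x$biomass), 100 * nf))
  invisible(x)
}

#' Construct a plot cluster
#'
#' @param plot_id identifier.
#' @param centers matrix of subplot center coordinates (4 x 2 for the
#'   clustered designs, 1 x 2 for the single-plot design).
#' @param mode `"FIA"`, `"NFI"`, or `"FIA_LIKE"`.
#' @param subplot_area area of each subplot in m^2.
#' @param spacing center-to-satellite spacing in m.
#' @return object of class `plot_cluster`.
#' @export
plot_cluster <- function(plot_id, centers, mode = "FIA",
                         subplot_area = if (mode == "NFI") 400 else 168,
                         spacing = 7) {
  mode <- match.arg(mode, c("FIA", "NFI", "FIA_LIKE"))
  centers <- matrix(as.numeric(centers), ncol = 2)
  n_expected <- if (mode == "NFI") 1L else 4L
  if (nrow(centers) != n_expected) {
    stop(sprintf("%s clusters must have exactly %d subplot center(s)",
                 mode, n_expected), call. = FALSE)
  }
  structure(list(plot_id = plot_id, centers = centers, mode = mode,
                 subplot_area = subplot_area, spacing = spacing),
            class = "plot_cluster")
}

#' Total sampled area of a cluster (m^2)
#' @param cluster a [plot_cluster()].
#' @export
cluster_sampled_area <- function(cluster) {
  nrow(cluster$centers) * cluster$subplot_area
}

subplot_offsets <- function(spacing) {
  az <- c(0, 120, 240) * pi / 180
  rbind(c(0, 0), cbind(spacing * sin(az), spacing * cos(az)))
}

#' Lay out a systematic plot network
#'
#' Places `n_plots` cluster centers on a systematic lattice with a common
#' random start, the standard design for regional inventories. Clustered
#' modes (`FIA`, `FIA_LIKE`) attach four 168 m^2 subplots — a center and
#' three satellites spaced `spacing` m at azimuths 0/120/240 degrees; `NFI`
#' mode uses a single 400 m^2 center plot. `FIA_LIKE` snaps each cluster to
#' the nearest forest-labeled pixel of `surface` (placement restricted to
#' forest, as when plots are installed inside mapped forest cover).
#'
#' @param grid a [grid_spec()].
#' @param n_plots number of plots (>= 1; must not exceed the pixel count).
#' @param mode `"FIA"`, `"NFI"`, or `"FIA_LIKE"`.
#' @param seed RNG seed for the random lattice start.
#' @param surface a `true_surface`, required for `FIA_LIKE`.
#' @param spacing subplot spacing in m (default 7).
#' @return list of [plot_cluster()] objects.
#' @export
generate_plot_network <- function(grid, n_plots, mode = "FIA", seed = 1,
                                  surface = NULL, spacing = 7) {
  stopifnot(inherits(grid, "grid_spec"))
  mode <- match.arg(mode, c("FIA", "NFI", "FIA_LIKE"))
  if (n_plots < 1) stop("n_plots must be >= 1", call. = FALSE)
  if (n_plots > grid$n_rows * grid$n_cols) {
    stop("n_plots exceeds the number of grid pixels", call. = FALSE)
  }
  set.seed(seed)
  ext <- grid_extent(grid)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  margin <- spacing + 1
  kx <- max(1L, ceiling(sqrt(n_plots * W / H)))
  ky <- ceiling(n_plots / kx)
  step_x <- W / kx; step_y <- H / ky
  off <- c(stats::runif(1, 0, step_x), stats::runif(1, 0, step_y))
  gridpts <- expand.grid(ix = seq_len(kx) - 1L, iy = seq_len(ky) - 1L)
  cx <- ext["xmin"] + off[1] + gridpts$ix * step_x
  cy <- ext["ymin"] + off[2] + gridpts$iy * step_y
  cx <- pmin(pmax(cx, ext["xmin"] + margin), ext["xmax"] - margin)
  cy <- pmin(pmax(cy, ext["ymin"] + margin), ext["ymax"] - margin)
  keep <- seq_len(n_plots)
  cx <- cx[keep]; cy <- cy[keep]

  if (mode == "FIA_LIKE") {
    if (is.null(surface)) stop("FIA_LIKE placement requires a surface", call. = FALSE)
    pc <- pixel_centers(grid)
    forest <- pc[surface$condition[cbind(pc$row, pc$col)] == "forest", ]
    if (nrow(forest) == 0L) stop("surface has no forest pixels", call. = FALSE)
    for (i in seq_along(cx)) {
      j <- which.min((forest$x - cx[i])^2 + (forest$y - cy[i])^2)
      cx[i] <- min(max(forest$x[j], ext["xmin"] + margin), ext["xmax"] - margin)
      cy[i] <- min(max(forest$y[j], ext["ymin"] + margin), ext["ymax"] - margin)
    }
  }

  offs <- if (mode == "NFI") matrix(0, 1, 2) else subplot_offsets(spacing)
  lapply(seq_len(n_plots), function(i) {
    centers <- cbind(cx[i] + offs[, 1], cy[i] + offs[, 2])
    plot_cluster(plot_id = i, centers = centers, mode = mode, spacing = spacing)
  })
}

#' Stand-structure parameters for the tree generator
#'
#' @param weibull_shape,weibull_scale parameters of the Weibull DBH
#'   distribution (cm). Defaults shape 2, scale 20 give a right-skewed
#'   diameter distribution with mean about 17.7 cm, typical of mixed
#'   second-growth stands.
#' @param species_mix named proportions over species groups (must sum to 1).
#' @param min_dbh smallest generated stem (cm), the usual 2.54 cm (1 in)
#'   inventory threshold.
#' @return object of class `stand_params`.
#' @export
stand_params <- function(weibull_shape = 2, weibull_scale = 20,
                         species_mix = c(mixed_hardwood = 0.40,
                                         hard_maple_oak_hickory_beech = 0.20,
                                         soft_maple_birch = 0.15,
                                         pine = 0.25),
                         min_dbh = 2.54) {
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stop("weibull parameters must be positive", call. = FALSE)
  }
  if (abs(sum(species_mix) - 1) > 1e-8) {
    stop("species_mix proportions must sum to 1", call. = FALSE)
  }
  structure(list(weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 species_mix = species_mix, min_dbh = min_dbh),
            class = "stand_params")
}

# E[exp(b0 + b1 ln D)] for D ~ Weibull(shape, scale): exp(b0) scale^b1 G(1+b1/shape)
mean_tree_biomass_kg <- function(stand, registry) {
  groups <- names(stand$species_mix)
  kg <- vapply(groups, function(g) {
    eq <- lookup_equation(registry, "LN_LN", g)
    exp(eq$coefficients$b0) * stand$weibull_scale^eq$coefficients$b1 *
      gamma(1 + eq$coefficients$b1 / stand$weibull_shape)
  }, numeric(1))
  sum(stand$species_mix * kg)
}

# simple regional height model feeding the CRM chain
bole_height_m <- function(dbh, noise_sd = 0.08) {
  total <- 1.37 + 28 * (1 - exp(-0.045 * dbh))
  0.65 * total * exp(stats::rnorm(length(dbh), 0, noise_sd))
}

species_for_group <- function(group, n) {
  pool <- switch(group,
    mixed_hardwood = c("tulip_poplar", "sweetgum", "black_cherry", "ash"),
    hard_maple_oak_hickory_beech = c("white_oak", "red_oak", "hickory"),
    soft_maple_birch = c("red_maple", "river_birch"),
    pine = c("loblolly_pine", "virginia_pine"),
    group)
  sample(pool, n, replace = TRUE)
}

#' Generate a tree list for a plot cluster
#'
#' For each subplot, the local true biomass density sets the expected stand
#' mass on the subplot; stem count is Poisson with mean (subplot mass /
#' expected single-tree biomass), DBH is Weibull, species are drawn from the
#' stand mixture, each tree's true biomass comes from the generalized ln-ln
#' equation of its group, and every tree inherits the condition label of its
#' pixel. Bole heights follow a saturating height-diameter curve with
#' lognormal noise so the CRM family is exercisable.
#'
#' @param cluster a [plot_cluster()] (must lie inside the surface extent).
#' @param surface a `true_surface`.
#' @param stand a [stand_params()].
#' @param seed RNG seed.
#' @param registry registry providing the group ln-ln equations used as the
#'   generating truth.
#' @return tree-record data.frame with the standard columns plus
#'   `species` and `true_biomass_kg`.
#' @export
generate_tree_list <- function(cluster, surface, stand = stand_params(),
                               seed = 1,
                               registry = default_equation_registry()) {
  stopifnot(inherits(cluster, "plot_cluster"), inherits(surface, "true_surface"))
  set.seed(seed)
  px <- locate_pixel(surface$grid, cluster$centers[, 1], cluster$centers[, 2])
  ebar <- mean_tree_biomass_kg(stand, registry)
  groups <- names(stand$species_mix)
  rows <- list()
  for (s in seq_len(nrow(cluster$centers))) {
    dens <- surface$biomass[px$row[s], px$col[s]]        # Mg/ha
    cond <- surface$condition[px$row[s], px$col[s]]
    mass_kg <- dens * cluster$subplot_area / 10000 * 1000
    n <- stats::rpois(1, mass_kg / ebar)
    if (n == 0L) next
    dbh <- pmax(stand$min_dbh,
                stats::rweibull(n, stand$weibull_shape, stand$weibull_scale))
    grp <- sample(groups, n, replace = TRUE, prob = stand$species_mix)
    sp <- vapply(grp, function(g) species_for_group(g, 1L), character(1),
                 USE.NAMES = FALSE)
    kg <- vapply(seq_len(n), function(i) {
      eq <- lookup_equation(registry, "LN_LN", grp[i])
      as.numeric(predict_biomass_lnln(dbh[i], eq))
    }, numeric(1))
    rows[[s]] <- data.frame(
      plot_id = cluster$plot_id, subplot_id = s, condition = cond,
      species_group = grp, species = sp, dbh_cm = dbh,
      bole_height_m = bole_height_m(dbh), true_biomass_kg = kg
    )
  }
  if (!length(rows)) {
    return(data.frame(plot_id = integer(), subplot_id = integer(),
                      condition = character(), species_group = character(),
                      species = character(), dbh_cm = numeric(),
                      bole_height_m = numeric(), true_biomass_kg = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate canopy-structure metric rasters from a biomass surface
#'
#' Each metric is a monotone power transform of true biomass plus Gaussian
#' noise: `m_k = b_k * biomass^exponent + e_k`. Sharing the same transformed
#' base makes the metrics mutually correlated, as height percentiles,
#' density metrics and canopy cover derived from one point cloud are. When
#' `target_r2` is given, the noise SD is calibrated by bisection so an
#' ordinary linear fit of biomass on the first metric attains that R^2
#' (refit after generation).
#'
#' @param surface a `true_surface`.
#' @param link_params list with `exponent` (> 0) and `noise_sd` (>= 0, in
#'   metric units).
#' @param n_metrics number of metric rasters (>= 1).
#' @param seed RNG seed.
#' @param target_r2 optional R^2 target for the biomass~metric linear fit.
#' @return list of [grid_raster()]s with attributes `noise_sd` and
#'   `achieved_r2`.
#' @export
generate_lidar_metrics <- function(surface,
                                   link_params = list(exponent = 0.5,
                                                      noise_sd = 1),
                                   n_metrics = 2, seed = 1,
                                   target_r2 = NULL) {
  stopifnot(inherits(surface, "true_surface"))
  if (n_metrics < 1) stop("n_metrics must be >= 1", call. = FALSE)
  if (link_params$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  b <- as.vector(surface$biomass)
  base <- b^link_params$exponent
  slopes <- 1 + 0.3 * (seq_len(n_metrics) - 1)
  noise <- matrix(stats::rnorm(length(b) * n_metrics), ncol = n_metrics)
  sd_use <- link_params$noise_sd
  r2_of <- function(s) {
    m1 <- slopes[1] * base + s * noise[, 1]
    summary(stats::lm(b ~ m1))$r.squared
  }
  if (!is.null(target_r2)) {
    lo <- 0; hi <- max(stats::sd(base), 1e-6)
    while (r2_of(hi) > target_r2) hi <- hi * 2
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (r2_of(mid) > target_r2) lo <- mid else hi <- mid
    }
    sd_use <- (lo + hi) / 2
  }
  out <- lapply(seq_len(n_metrics), function(k) {
    v <- slopes[k] * base + sd_use * noise[, k]
    grid_raster(matrix(v, surface$grid$n_rows, surface$grid$n_cols),
                surface$grid)
  })
  attr(out, "noise_sd") <- sd_use
  attr(out, "achieved_r2") <- r2_of(sd_use)
  out
}

#' Apply an inventory measurement protocol to a tree list
#'
#' Reproduces the censoring behavior of the inventory designs: `FIA` drops
#' every tree whose condition is nonforest (the plot itself is retained,
#' possibly with zero trees — trees on nonforest land are simply not
#' measured); `NFI` keeps all trees on the single 400 m^2 center plot
#' (subplot 1); `FIA_LIKE` keeps everything, because those plots are placed
#' in forest to begin with.
#'
#' @param trees tree-record data.frame.
#' @param mode `"FIA"`, `"NFI"`, or `"FIA_LIKE"`.
#' @return the retained tree records.
#' @export
apply_inventory_protocol <- function(trees, mode) {
  mode <- match.arg(mode, c("FIA", "NFI", "FIA_LIKE"))
  check_tree_table(trees)
  switch(mode,
         FIA = trees[trees$condition != "nonforest", , drop = FALSE],
         NFI = trees[trees$subplot_id == 1L, , drop = FALSE],
         FIA_LIKE = trees)
}
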