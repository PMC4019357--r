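#' Simulate a calibrated population around an allometric regression line
#'
#' Draws `size` DBH values over the equation's validity range and generates
#' biomass as the ln-ln prediction plus Gaussian noise on the log scale
#' (keeping biomass positive and uncertainty growing with tree size). The
#' log-scale noise SD is calibrated by bisection until the R^2 of an ln-ln
#' regression refit to the simulated points matches the source equation's
#' R^2 within `r2_tolerance`. One standard-normal noise vector is drawn once
#' and rescaled during the search, which makes the refit R^2 a deterministic,
#' strictly decreasing function of the noise SD, so the bisection always
#' converges.
#'
#' @param eq an ln-ln [allometric_equation()] with a finite `r_squared`.
#' @param size population size (default 10000).
#' @param r2_tolerance absolute tolerance on the refit R^2 (default 0.005).
#' @param seed RNG seed.
#' @param max_iter bisection iteration cap.
#' @return object of class `sim_population`: list with `dbh`, `biomass`
#'   (kg), `noise_sd` (log scale), `achieved_r2`, `eq`.
#' @export
simulate_population <- function(eq, size = 10000, r2_tolerance = 0.005,
                                seed = 1, max_iter = 80) {
  stopifnot(inherits(eq, "allometric_equation"))
  target <- eq$r_squared
  if (!is.finite(target) || target <= 0 || target > 1) {
    stop("equation must carry r_squared in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  dbh <- stats::runif(size, eq$dbh_range[1], eq$dbh_range[2])
  mu <- eq$coefficients$b0 + eq$coefficients$b1 * log(dbh)
  e <- stats::rnorm(size)
  r2_at <- function(s) {
    y <- mu + s * e
    stats::cor(y, log(dbh))^2
  }
  if (target == 1) {
    s_use <- 0
  } else {
    lo <- 0; hi <- stats::sd(mu)
    it <- 0L
    while (r2_at(hi) > target) {
      hi <- hi * 2; it <- it + 1L
      if (it > max_iter) stop("noise calibration failed to bracket the target R^2",
                              call. = FALSE)
    }
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      if (r2_at(mid) > target) lo <- mid else hi <- mid
      if (abs(r2_at(mid) - target) < r2_tolerance / 4) break
    }
    s_use <- (lo + hi) / 2
  }
  achieved <- r2_at(s_use)
  if (abs(achieved - target) > r2_tolerance) {
    stop(sprintf("noise calibration did not converge (achieved R^2 %.4f, target %.4f)",
                 achieved, target), call. = FALSE)
  }
  structure(list(dbh = dbh, biomass = exp(mu + s_use * e),
                 noise_sd = s_use, achieved_r2 = achieved, eq = eq),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> n=%d, %s/%s, log-noise sd %.4f, refit R2 %.4f\n",
              length(x$dbh), x$eq$family, x$eq$group, x$noise_sd, x$achieved_r2))
  invisible(x)
}

#' Evaluate a standard-error function
#'
#' @param sef an `se_function`.
#' @param dbh DBH in cm.
#' @return SE of predicted biomass, in kg.
#' @export
se_eval <- function(sef, dbh) {
  stopifnot(inherits(sef, "se_function"))
  sef$a * dbh^sef$b
}

se_function <- function(group, a, b, n_subsets = NA_integer_) {
  if (a < 0) stop("SE amplitude must be >= 0", call. = FALSE)
  structure(list(group = group, a = a, b = b, n_subsets = n_subsets,
                 form = "SE(dbh) = a * dbh^b"),
            class = "se_function")
}

#' @export
print.se_function <- function(x, ...) {
  cat(sprintf("<se_function> %s: SE(dbh) = %.4g * dbh^%.4g (mean of %s subsets)\n",
              x$group, x$a, x$b, x$n_subsets))
  invisible(x)
}

fit_power_se <- function(dbh, abs_resid, n_bins) {
  n <- length(dbh)
  n_bins <- max(2L, min(n_bins, n %/% 3L))
  o <- order(dbh)
  bin <- ceiling(seq_along(o) / (n / n_bins))
  d_mid <- tapply(dbh[o], bin, stats::median)
  # half-normal correction: E|N(0,s)| = s * sqrt(2/pi)
  se_bin <- sqrt(pi / 2) * tapply(abs_resid[o], bin, mean)
  pos <- se_bin > 1e-12 & d_mid > 0
  if (sum(pos) < 2L) return(c(a = 0, b = 0))
  fit <- stats::lm(log(se_bin[pos]) ~ log(d_mid[pos]))
  c(a = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

#' Derive the mean standard-error function for a species group
#'
#' The subset-resampling procedure: from a simulated population calibrated
#' to the source equation's R^2, repeatedly (at least 100 times) draw as
#' many DBH values as the source regression had observations from a Weibull
#' diameter distribution, take the nearest simulated points, and fit a
#' two-parameter power law `SE(dbh) = a * dbh^b` by least squares to the
#' binned absolute prediction residuals (up to 20 equal-count DBH bins,
#' half-normal corrected so the fit targets a residual SD). The returned
#' function is the parameter-wise mean over all subset fits.
#'
#' @param eq an ln-ln [allometric_equation()] with `n_obs` set.
#' @param weibull list with `shape` and `scale` of the DBH draw; default
#'   shape 2 and scale placing the Weibull mean at the midpoint of the
#'   equation's validity range.
#' @param n_subsets number of subsets (>= 100, the procedural minimum).
#' @param seed RNG seed.
#' @param pop optional pre-built population: a list with `dbh` and `biomass`
#'   (e.g. a [simulate_population()] result, or a designed noise structure
#'   for calibration checks).
#' @param n_bins maximum number of equal-count DBH bins (default 20).
#' @return an `se_function`.
#' @export
derive_mean_se_function <- function(eq, weibull = NULL, n_subsets = 100,
                                    seed = 1, pop = NULL, n_bins = 20) {
  stopifnot(inherits(eq, "allometric_equation"))
  if (n_subsets < 100) {
    stop("n_subsets must be >= 100 (procedural minimum)", call. = FALSE)
  }
  if (is.na(eq$n_obs) || eq$n_obs < 2) stop("equation must carry n_obs >= 2", call. = FALSE)
  if (is.null(weibull)) {
    weibull <- list(shape = 2,
                    scale = mean(eq$dbh_range) / gamma(1.5))
  }
  if (is.null(pop)) {
    pop <- simulate_population(eq, seed = seed + 1L)
  }
  set.seed(seed)
  o <- order(pop$dbh)
  pd <- pop$dbh[o]; pb <- pop$biomass[o]
  pred <- exp(eq$coefficients$b0 + eq$coefficients$b1 * log(pd))
  resid_abs <- abs(pb - pred)
  params <- matrix(NA_real_, n_subsets, 2L)
  for (k in seq_len(n_subsets)) {
    d <- stats::rweibull(eq$n_obs, weibull$shape, weibull$scale)
    d <- pmin(pmax(d, min(pd)), max(pd))
    idx <- findInterval(d, pd, all.inside = TRUE)
    # findInterval gives the left neighbor; keep the nearer of the two
    right <- pmin(idx + 1L, length(pd))
    use_right <- (pd[right] - d) < (d - pd[idx])
    idx[use_right] <- right[use_right]
    params[k, ] <- fit_power_se(pd[idx], resid_abs[idx], n_bins)
  }
  se_function(group = eq$group, a = mean(params[, 1]), b = mean(params[, 2]),
              n_subsets = n_subsets)
}

#' Propagate allometric error to a plot-level 95% confidence interval
#'
#' Monte Carlo propagation applied tree by tree: in each replicate every
#' tree's predicted biomass is perturbed by an independent draw from
#' `Normal(prediction, SE(dbh))` (its group's standard-error function),
#' truncated at zero, and the perturbed trees are summed to a plot density;
#' the 2.5th and 97.5th percentiles across replicates bound the interval.
#' The interval therefore depends on the mixture of species groups on the
#' plot and their diameters. The reported mean is the deterministic
#' allometric plot density.
#'
#' @param trees tree-record data.frame.
#' @param se_functions named list (by species group) of `se_function`s.
#' @param registry an [equation_registry()].
#' @param sampled_area sampled area in m^2.
#' @param n_reps Monte Carlo replicates (>= 1000; default 10000).
#' @param seed RNG seed.
#' @param family allometric family for the point predictions.
#' @param shared_error if `TRUE`, all trees in a replicate share one error
#'   draw (a plot-level error component for sensitivity runs) instead of
#'   independent per-tree draws.
#' @return object of class `plot_ci`: list with `plot_id`, `mean`, `lower`,
#'   `upper` (Mg/ha) and `n_reps`.
#' @export
propagate_plot_ci <- function(trees, se_functions, registry,
                              sampled_area, n_reps = 10000, seed = 1,
                              family = "LN_LN", shared_error = FALSE) {
  if (n_reps < 1000) stop("n_reps must be >= 1000", call. = FALSE)
  plot_id <- if (nrow(trees)) trees$plot_id[1] else NA
  if (nrow(trees) == 0L) {
    return(structure(list(plot_id = plot_id, mean = 0, lower = 0, upper = 0,
                          n_reps = n_reps), class = "plot_ci"))
  }
  check_tree_table(trees)
  missing <- setdiff(unique(trees$species_group), names(se_functions))
  if (length(missing)) {
    stop("no SE function for species group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  pred <- tree_biomass(trees, family = family, registry = registry)
  se <- vapply(seq_len(nrow(trees)), function(i) {
    se_eval(se_functions[[trees$species_group[i]]], trees$dbh_cm[i])
  }, numeric(1))
  n <- nrow(trees)
  Z <- if (shared_error) {
    matrix(stats::rnorm(n_reps), n_reps, n)
  } else {
    matrix(stats::rnorm(n_reps * n), n_reps, n)
  }
  perturbed <- pmax(sweep(Z, 2L, se, `*`) + matrix(pred, n_reps, n, byrow = TRUE), 0)
  to_mgha <- 1 / 1000 / (sampled_area / 10000)
  dens <- rowSums(perturbed) * to_mgha
  q <- stats::quantile(dens, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(plot_id = plot_id, mean = sum(pred) * to_mgha,
                 lower = q[1], upper = q[2], n_reps = n_reps),
            class = "plot_ci")
}

#' @export
print.plot_ci <- function(x, ...) {
  cat(sprintf("<plot_ci> plot %s: %.1f Mg/ha (95%% CI %.1f-%.1f, %d reps)\n",
              format(x$plot_id), x$mean, x$lower, x$upper, x$n_reps))
  invisible(x)
}

#' Plot CIs for a multi-plot tree table
#'
#' Splits a tree table by `plot_id`, propagates the allometric error for
#' each plot and returns one row per plot. Plots listed in `plot_ids` but
#' absent from the table (fully censored plots) get a zero-biomass,
#' zero-width interval.
#'
#' @inheritParams propagate_plot_ci
#' @param plot_ids optional full set of plot ids.
#' @return data.frame with columns `plot_id`, `mean_mgha`, `lo95`, `hi95`.
#' @export
plot_ci_table <- function(trees, se_functions, registry, sampled_area,
                          n_reps = 10000, seed = 1, family = "LN_LN",
                          plot_ids = NULL) {
  ids <- plot_ids %||% sort(unique(trees$plot_id))
  rows <- lapply(seq_along(ids), function(i) {
    tr <- trees[trees$plot_id == ids[i], , drop = FALSE]
    ci <- propagate_plot_ci(tr, se_functions, registry, sampled_area,
                            n_reps = n_reps, seed = seed + i, family = family)
    data.frame(plot_id = ids[i], mean_mgha = ci$mean,
               lo95 = ci$lower, hi95 = ci$upper)
  })
  do.call(rbind, rows)
}
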