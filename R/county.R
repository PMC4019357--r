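county_estimate <- function(mean, mean_ci, total, total_ci, method, n) {
  if (isTRUE(diff(mean_ci) < 0) || isTRUE(diff(total_ci) < 0)) {
    stop("confidence bounds are out of order", call. = FALSE)
  }
  structure(list(mean = mean, mean_ci = mean_ci,
                 total = total, total_ci = total_ci,
                 method = method, n = n),
            class = "county_estimate")
}

#' @export
print.county_estimate <- function(x, ...) {
  cat(sprintf("<county_estimate> [%s] mean %.1f Mg/ha (%.1f, %.1f); total %.3g Tg (%.3g, %.3g); n=%d\n",
              x$method, x$mean, x$mean_ci[1], x$mean_ci[2],
              x$total, x$total_ci[1], x$total_ci[2], x$n))
  invisible(x)
}

#' Design-based county estimate from plot biomass
#'
#' Sample mean of the plot densities with a t-interval on n - 1 degrees of
#' freedom (the default; a bootstrap-percentile interval is available), then
#' expansion to a county total: `Tg = Mg/ha x area_ha x 1e-6`. The CI bounds
#' expand by the same factor.
#'
#' @param plot_values plot biomass densities (Mg/ha), n >= 2.
#' @param county_area county area in hectares.
#' @param conf confidence level (default 0.95).
#' @param ci_method `"t"` (default) or `"bootstrap"` percentile.
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return a `county_estimate` with `method = "DESIGN"`.
#' @export
design_estimate <- function(plot_values, county_area, conf = 0.95,
                            ci_method = c("t", "bootstrap"),
                            n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  n <- length(plot_values)
  if (n < 2) stop("need at least 2 plots for a design-based CI", call. = FALSE)
  if (county_area <= 0) stop("county_area must be positive", call. = FALSE)
  m <- mean(plot_values)
  if (ci_method == "t") {
    se <- stats::sd(plot_values) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    ci <- c(m - tq * se, m + tq * se)
  } else {
    set.seed(seed)
    bm <- replicate(n_boot, mean(sample(plot_values, n, replace = TRUE)))
    ci <- unname(stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  f <- county_area * 1e-6   # Mg/ha -> Tg over the county
  county_estimate(mean = m, mean_ci = ci, total = m * f, total_ci = ci * f,
                  method = "DESIGN", n = n)
}

#' County estimate from map pixels sampled at plot locations
#'
#' Mimics the field sample design on the map: extract the plot-level map
#' value for every cluster ([extract_plot_prediction()]), then apply the
#' design-based estimator to those values.
#'
#' @param raster biomass map ([grid_raster()], Mg/ha).
#' @param clusters plot network.
#' @param county_area county area in hectares.
#' @param ... passed to [design_estimate()].
#' @return a `county_estimate` with `method = "PIXEL_SAMPLE"`.
#' @export
pixel_sample_estimate <- function(raster, clusters, county_area, ...) {
  if (!length(clusters)) stop("need at least 2 plots for a design-based CI", call. = FALSE)
  vals <- extract_network_predictions(raster, clusters)
  est <- design_estimate(as.numeric(vals), county_area, ...)
  est$method <- "PIXEL_SAMPLE"
  est
}

#' County total by summing map pixels
#'
#' Total biomass as the pixel sum times the per-pixel area in hectares
#' (0.09 ha for 30-m pixels), converted to Tg; with lower/upper bands the
#' bounds are summed the same way. A pixel size other than 30 m is allowed —
#' the conversion is recomputed from the actual pixel area and noted.
#'
#' @param raster biomass map ([grid_raster()], Mg/ha) or a
#'   `predictive_raster` with per-pixel bands.
#' @return a `county_estimate` with `method = "PIXEL_SUM"` (mean over
#'   pixels; CI only when bands are available).
#' @export
pixel_sum_estimate <- function(raster) {
  bands <- if (inherits(raster, "predictive_raster")) {
    list(mean = raster$mean, lower = raster$lower, upper = raster$upper)
  } else {
    stopifnot(inherits(raster, "grid_raster"))
    list(mean = raster)
  }
  g <- bands$mean$grid
  pixel_ha <- g$pixel_size^2 / 10000
  if (abs(pixel_ha - 0.09) > 1e-12) {
    message(sprintf("pixel size %.4g m: using %.6g ha/pixel instead of 0.09",
                    g$pixel_size, pixel_ha))
  }
  tot <- function(r) sum(r$values, na.rm = TRUE) * pixel_ha * 1e-6
  n_pix <- sum(is.finite(bands$mean$values))
  total <- tot(bands$mean)
  ci <- if (!is.null(bands$lower)) c(tot(bands$lower), tot(bands$upper))
        else c(total, total)
  mean_v <- mean(bands$mean$values, na.rm = TRUE)
  mean_ci <- if (!is.null(bands$lower)) {
    c(mean(bands$lower$values, na.rm = TRUE),
      mean(bands$upper$values, na.rm = TRUE))
  } else c(mean_v, mean_v)
  county_estimate(mean = mean_v, mean_ci = mean_ci, total = total,
                  total_ci = ci, method = "PIXEL_SUM", n = n_pix)
}

#' Nonforest share of total biomass
#'
#' Decomposes an all-tree total against a forest-only (censored) total:
#' the biomass on land in nonforest condition and its share of the total.
#'
#' @param total_all_trees total biomass of all trees (Tg).
#' @param total_forest_only total with nonforest-condition trees censored
#'   (Tg); must not exceed `total_all_trees`.
#' @return list with `nonforest_tg` and `nonforest_pct`.
#' @export
nonforest_share <- function(total_all_trees, total_forest_only) {
  if (total_forest_only < 0 || total_all_trees < total_forest_only) {
    stop("totals must satisfy all-trees >= forest-only >= 0", call. = FALSE)
  }
  diff <- total_all_trees - total_forest_only
  list(nonforest_tg = diff,
       nonforest_pct = if (total_all_trees > 0) 100 * diff / total_all_trees else 0)
}

#' Gap between two county estimates
#'
#' Signed difference of totals, percent difference relative to the second
#' estimate, and whether the first total falls inside the second's 95%
#' interval.
#'
#' @param estimate_a,estimate_b `county_estimate`s for the same county.
#' @return list with `difference_tg`, `pct_difference`, `within_ci`.
#' @export
estimate_gap <- function(estimate_a, estimate_b) {
  stopifnot(inherits(estimate_a, "county_estimate"),
            inherits(estimate_b, "county_estimate"))
  diff <- estimate_a$total - estimate_b$total
  list(difference_tg = diff,
       pct_difference = 100 * diff / estimate_b$total,
       within_ci = estimate_a$total >= estimate_b$total_ci[1] &&
                   estimate_a$total <= estimate_b$total_ci[2])
}

#' Assemble a county estimate from printed summary numbers
#'
#' Convenience constructor for inter-comparison arithmetic when only the
#' reported mean/total and intervals of an estimate are available (e.g.
#' re-deriving published decompositions from a summary table).
#'
#' @param total total biomass (Tg).
#' @param total_ci optional 95% bounds on the total (Tg).
#' @param mean mean density (Mg/ha), optional.
#' @param mean_ci optional bounds on the mean.
#' @param method method label.
#' @param n sample size behind the estimate.
#' @return a `county_estimate`.
#' @export
county_estimate_from_totals <- function(total, total_ci = c(total, total),
                                        mean = NA_real_,
                                        mean_ci = c(mean, mean),
                                        method = "REPORTED", n = NA_integer_) {
  county_estimate(mean = mean, mean_ci = mean_ci, total = total,
                  total_ci = total_ci, method = method, n = as.integer(n))
}
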