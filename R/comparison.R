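#' Extract a map prediction for a plot cluster
#'
#' Reads the map pixel containing each subplot center (half-open pixel
#' convention, see [locate_pixel()]) and averages the values — for the
#' clustered four-subplot design the mean of the four pixel values, for the
#' single-plot design the one center pixel. A no-data pixel is an error of
#' class `forestAGB_missing_data` so callers can exclude and log the pair
#' rather than zero-fill it.
#'
#' @param raster a [grid_raster()] of biomass (Mg/ha).
#' @param cluster a [plot_cluster()].
#' @return mean mapped biomass at the plot (Mg/ha).
#' @export
extract_plot_prediction <- function(raster, cluster) {
  stopifnot(inherits(raster, "grid_raster"), inherits(cluster, "plot_cluster"))
  px <- locate_pixel(raster$grid, cluster$centers[, 1], cluster$centers[, 2])
  v <- raster$values[cbind(px$row, px$col)]
  if (any(is.na(v))) {
    stop(structure(class = c("forestAGB_missing_data", "error", "condition"),
                   list(message = sprintf("plot %s hits %d no-data pixel(s)",
                                          format(cluster$plot_id), sum(is.na(v))),
                        call = NULL)))
  }
  mean(v)
}

#' Extract map predictions for a plot network
#'
#' Applies [extract_plot_prediction()] to every cluster; pairs hitting
#' no-data pixels are excluded with a message and recorded in the
#' `excluded` attribute.
#'
#' @param raster a [grid_raster()].
#' @param clusters list of [plot_cluster()]s.
#' @return named numeric vector of plot predictions (Mg/ha), with attribute
#'   `excluded` (plot ids dropped over no-data).
#' @export
extract_network_predictions <- function(raster, clusters) {
  out <- rep(NA_real_, length(clusters))
  names(out) <- vapply(clusters, function(cl) format(cl$plot_id), character(1))
  dropped <- character(0)
  for (i in seq_along(clusters)) {
    val <- tryCatch(extract_plot_prediction(raster, clusters[[i]]),
                    forestAGB_missing_data = function(e) {
                      message("excluding plot over no-data: ",
                              conditionMessage(e))
                      NA_real_
                    })
    if (is.na(val)) dropped <- c(dropped, names(out)[i])
    out[i] <- val
  }
  res <- out[!is.na(out)]
  attr(res, "excluded") <- dropped
  res
}

#' Agreement regression of mapped on field biomass
#'
#' Ordinary least squares of the mapped values (y) on the field values (x):
#' slope and R^2; a slope above 1 means the map over-predicts. RMSE is
#' computed from the raw pair differences `sqrt(mean((mapped - field)^2))`
#' by default — a direct measure of map error — with the regression-residual
#' variant available via `rmse_type`.
#'
#' @param field field plot biomass (Mg/ha).
#' @param mapped extracted map biomass (Mg/ha), paired with `field`.
#' @param rmse_type `"difference"` (default) or `"residual"`.
#' @return list with `r_squared`, `slope`, `intercept`, `rmse`, `n_pairs`.
#' @export
agreement_regression <- function(field, mapped,
                                 rmse_type = c("difference", "residual")) {
  rmse_type <- match.arg(rmse_type)
  n <- length(field)
  if (n < 3 || length(mapped) != n) {
    stop("need >= 3 paired observations", call. = FALSE)
  }
  if (stats::sd(field) == 0) {
    stop("field values have zero variance; the fit is undefined", call. = FALSE)
  }
  fit <- stats::lm(mapped ~ field)
  rmse <- if (rmse_type == "difference") {
    sqrt(mean((mapped - field)^2))
  } else {
    sqrt(mean(stats::residuals(fit)^2))
  }
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rmse = rmse, n_pairs = n)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the two empirical cumulative distribution
#' functions: 0 for identical samples, 1 for fully separated supports;
#' higher values reflect poorer distributional agreement. Ties are handled
#' exactly (the sup is taken over the pooled jump points).
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return KS statistic in [0, 1].
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pts <- sort(unique(c(sample_a, sample_b)))
  Fa <- findInterval(pts, sort(sample_a)) / length(sample_a)
  Fb <- findInterval(pts, sort(sample_b)) / length(sample_b)
  max(abs(Fa - Fb))
}

#' Fraction of overlapping confidence-interval pairs
#'
#' For paired field-plot and map-pixel 95% intervals, the fraction of pairs
#' whose closed intervals intersect (touching endpoints count as overlap).
#'
#' @param field_cis,pixel_cis paired interval sets of equal length: either
#'   data.frames with columns `lo95`/`hi95` (or `lower`/`upper`), or lists
#'   of objects carrying `lower` and `upper`.
#' @return proportion in [0, 1].
#' @export
ci_overlap_fraction <- function(field_cis, pixel_cis) {
  as_bounds <- function(x) {
    if (is.data.frame(x)) {
      lo <- x$lo95 %||% x$lower; hi <- x$hi95 %||% x$upper
    } else {
      lo <- vapply(x, function(ci) ci$lower, numeric(1))
      hi <- vapply(x, function(ci) ci$upper, numeric(1))
    }
    if (is.null(lo) || is.null(hi)) stop("cannot find interval bounds", call. = FALSE)
    if (any(lo > hi)) stop("malformed interval: lower bound exceeds upper", call. = FALSE)
    cbind(lo, hi)
  }
  a <- as_bounds(field_cis); b <- as_bounds(pixel_cis)
  if (nrow(a) != nrow(b)) stop("interval lists must be paired", call. = FALSE)
  mean(pmax(a[, 1], b[, 1]) <= pmin(a[, 2], b[, 2]))
}

#' Empirical CDF table
#'
#' Sorted unique values with their cumulative proportions, for
#' distributional comparison plots and for reading off quantiles such as
#' the sample median.
#'
#' @param sample non-empty numeric sample.
#' @return data.frame with `value` and `cum_prop`.
#' @export
cdf_table <- function(sample) {
  if (!length(sample)) stop("sample must be non-empty", call. = FALSE)
  v <- sort(unique(sample))
  data.frame(value = v,
             cum_prop = findInterval(v, sort(sample)) / length(sample))
}

#' Full plot-to-map comparison
#'
#' Pairs field plot values with map extractions over a plot network and
#' computes the agreement statistics in one pass; `exclude_nonforest` drops
#' purely nonforest (zero field biomass) pairs first, reproducing the
#' forest-conditions-only analysis variant.
#'
#' @param field_values named or plot-ordered field biomass (Mg/ha).
#' @param raster biomass map ([grid_raster()]).
#' @param clusters plot network matching `field_values`.
#' @param exclude_nonforest drop pairs with zero field biomass.
#' @return list with `r_squared`, `slope`, `rmse`, `ks`, `n_pairs`,
#'   `field`, `mapped`.
#' @export
compare_plots_map <- function(field_values, raster, clusters,
                              exclude_nonforest = FALSE) {
  mapped <- extract_network_predictions(raster, clusters)
  keep_ids <- names(mapped)
  ids <- vapply(clusters, function(cl) format(cl$plot_id), character(1))
  field <- field_values[match(keep_ids, ids)]
  if (exclude_nonforest) {
    nz <- field > 0
    field <- field[nz]; mapped <- mapped[nz]
  }
  reg <- agreement_regression(field, as.numeric(mapped))
  c(reg[c("r_squared", "slope", "rmse", "n_pairs")],
    list(ks = ks_statistic(field, as.numeric(mapped)),
         field = as.numeric(field), mapped = as.numeric(mapped)))
}
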