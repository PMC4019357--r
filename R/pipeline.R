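#' Derive a stage seed from the master seed
#'
#' Stage seeds are a deterministic hash of the master seed and the stage
#' name, so individual stages can be re-run in isolation with the stream
#' they had inside the full pipeline. Kept below 2^31 - 1.
#'
#' @param master master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1003951
  as.integer((abs(master) %% 1e6) * 2039 + h) %% 2147483647L
}

#' Pipeline configuration
#'
#' All defaults are sufficient for a no-argument desk-scale demo run. The
#' landscape/inventory defaults describe the study conditions the package
#' emulates: a 30-m landscape with 40% of the area in nonforest condition
#' carrying 25% of the biomass, clustered four-subplot plots (168 m^2
#' subplots spaced 7 m), Weibull(2, 20 cm) diameters, and canopy metrics
#' calibrated to an R^2 of 0.67 against true biomass.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param grid a [grid_spec()].
#' @param surface surface-generator arguments.
#' @param stand a [stand_params()].
#' @param n_plots number of inventory plots.
#' @param registry_path optional equation-registry YAML (default: packaged
#'   registry).
#' @param n_subsets SE-function subsets per species group.
#' @param mc_reps Monte Carlo replicates per plot CI.
#' @param lidar canopy-metric generator arguments (`n_metrics`,
#'   `target_r2`).
#' @param mcmc spatial-model MCMC controls.
#' @param predict_draws posterior draws used for pixel prediction.
#' @param county_area_ha area represented by the landscape; default the
#'   grid area.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 20140508,
                            grid = grid_spec(40, 40, 30),
                            surface = list(spatial_params = list(sill = 2500,
                                                                 decay = 0.01,
                                                                 mean = 70),
                                           nonforest_fraction = 0.4,
                                           scattered_trees = TRUE,
                                           nonforest_biomass_share = 0.25),
                            stand = stand_params(),
                            n_plots = 60,
                            registry_path = NULL,
                            n_subsets = 100,
                            mc_reps = 10000,
                            lidar = list(n_metrics = 2, target_r2 = 0.67),
                            mcmc = list(n_iter = 4000, burn_in = 2000,
                                        thin = 4),
                            predict_draws = 200,
                            county_area_ha = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(stand, "stand_params"))
  if (n_plots < 2) stop("n_plots must be >= 2", call. = FALSE)
  cfg <- list(seed = seed, grid = grid, surface = surface, stand = stand,
              n_plots = n_plots, registry_path = registry_path,
              n_subsets = n_subsets, mc_reps = mc_reps, lidar = lidar,
              mcmc = mcmc, predict_draws = predict_draws,
              county_area_ha = county_area_ha %||%
                (grid$n_rows * grid$n_cols * grid$pixel_size^2 / 10000))
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full synthetic inter-comparison pipeline
#'
#' Stage order: landscape and canopy metrics; plot network and tree lists;
#' inventory censoring (all-tree vs forest-condition-only); allometric
#' family comparison; allometric-error SE functions and plot 95% CIs;
#' spatial-model and ensemble biomass maps; plot-to-map comparison; county
#' estimation with the nonforest decomposition. Deterministic under the
#' config's master seed (every stage seed derives from it).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tree/plot/CI tables
#'   (CSV), rasters (ESRI ASCII), and comparison/county reports (JSON) are
#'   written there.
#' @param verbose log one line per stage.
#' @return a `pipeline_report` list; see the fields in the source of
#'   [print.pipeline_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  registry <- if (is.null(config$registry_path)) default_equation_registry()
              else read_equation_registry(config$registry_path)
  seed_of <- function(stage) derive_seed(config$seed, stage)

  # --- landscape ---
  surface <- do.call(generate_biomass_surface,
                     c(list(grid = config$grid, seed = seed_of("surface")),
                       config$surface))
  pipeline_log(verbose, "surface", "mean %.1f Mg/ha, %.0f%% nonforest pixels",
               mean(surface$biomass), 100 * mean(surface$condition == "nonforest"))
  metrics <- generate_lidar_metrics(surface,
                                    n_metrics = config$lidar$n_metrics,
                                    seed = seed_of("lidar"),
                                    target_r2 = config$lidar$target_r2)
  pipeline_log(verbose, "lidar", "%d metrics, biomass~metric R2 %.3f",
               length(metrics), attr(metrics, "achieved_r2"))

  # --- plots and trees ---
  clusters <- generate_plot_network(config$grid, config$n_plots, "FIA",
                                    seed = seed_of("plots"))
  trees_all <- do.call(rbind, lapply(clusters, function(cl) {
    generate_tree_list(cl, surface, config$stand,
                       seed = seed_of(paste0("trees", cl$plot_id)),
                       registry = registry)
  }))
  trees_fia <- apply_inventory_protocol(trees_all, "FIA")
  pipeline_log(verbose, "inventory", "%d trees measured, %d after FIA censoring",
               nrow(trees_all), nrow(trees_fia))

  area <- cluster_sampled_area(clusters[[1]])
  ids <- vapply(clusters, function(cl) cl$plot_id, numeric(1))
  dens_of <- function(trees) {
    vapply(ids, function(id) {
      plot_biomass_density(trees[trees$plot_id == id, , drop = FALSE],
                           area, family = "LN_LN", registry = registry)
    }, numeric(1))
  }
  dens_all <- dens_of(trees_all)
  dens_fia <- dens_of(trees_fia)

  # --- allometric family comparison (plots with trees) ---
  plots_list <- split(trees_fia, trees_fia$plot_id)
  plots_list <- plots_list[vapply(plots_list, nrow, 1L) > 0]
  allom <- compare_allometry_choices(plots_list, registry, sampled_area = area)

  # --- allometric error propagation ---
  groups <- names(config$stand$species_mix)
  se_functions <- lapply(seq_along(groups), function(i) {
    derive_mean_se_function(lookup_equation(registry, "LN_LN", groups[i]),
                            n_subsets = config$n_subsets,
                            seed = seed_of(paste0("se", groups[i])))
  })
  names(se_functions) <- groups
  ci_tab <- plot_ci_table(trees_fia, se_functions, registry, area,
                          n_reps = config$mc_reps, seed = seed_of("plotci"),
                          plot_ids = ids)
  nonzero <- ci_tab$mean_mgha > 0
  ci_width <- ci_tab$hi95 - ci_tab$lo95
  ci_summary <- list(
    mean_width_mgha = mean(ci_width[nonzero]),
    mean_width_pct_of_mean = 100 * mean(ci_width[nonzero] /
                                          ci_tab$mean_mgha[nonzero])
  )
  pipeline_log(verbose, "plot-ci", "mean 95%% CI width %.1f Mg/ha (%.0f%% of plot mean)",
               ci_summary$mean_width_mgha, ci_summary$mean_width_pct_of_mean)

  # --- mapping ---
  plot_xy <- t(vapply(clusters, function(cl) cl$centers[1, ], numeric(2)))
  Xplots <- cbind(1, vapply(metrics, function(m) {
    as.numeric(extract_network_predictions(m, clusters))
  }, numeric(length(clusters))))
  colnames(Xplots) <- c("intercept", paste0("metric", seq_along(metrics)))
  fit <- fit_spatial_regression(dens_fia, Xplots, plot_xy,
                                mcmc = config$mcmc, seed = seed_of("mcmc"))
  pc <- pixel_centers(config$grid)
  Xpix <- cbind(1, vapply(metrics, function(m) {
    m$values[cbind(pc$row, pc$col)]
  }, numeric(nrow(pc))))
  colnames(Xpix) <- colnames(Xplots)
  pred <- predict_posterior(fit, Xpix, as.matrix(pc[, c("x", "y")]),
                            n_draws = config$predict_draws,
                            seed = seed_of("predict"))
  bay <- as_predictive_raster(pred, config$grid)
  rf <- fit_ensemble_baseline(dens_fia, Xplots[, -1, drop = FALSE],
                              X_new = Xpix[, -1, drop = FALSE],
                              seed = seed_of("rf"))
  rf_raster <- grid_raster(matrix(rf$predictions, config$grid$n_rows,
                                  config$grid$n_cols, byrow = TRUE),
                           config$grid)
  pipeline_log(verbose, "mapping", "BAY phi acceptance %.2f; RF OOB R2 %.2f",
               fit$acceptance_rate, rf$oob_r2)

  # --- comparison ---
  names(dens_fia) <- format(ids)
  comparison <- list(
    bay_all = compare_plots_map(dens_fia, bay$mean, clusters),
    bay_forest_only = compare_plots_map(dens_fia, bay$mean, clusters,
                                        exclude_nonforest = TRUE),
    rf_all = compare_plots_map(dens_fia, rf_raster, clusters)
  )
  pixel_cis <- data.frame(
    lo95 = as.numeric(extract_network_predictions(bay$lower, clusters)),
    hi95 = as.numeric(extract_network_predictions(bay$upper, clusters))
  )
  overlap <- ci_overlap_fraction(ci_tab[, c("lo95", "hi95")], pixel_cis)

  # --- county estimation ---
  A <- config$county_area_ha
  est_all <- design_estimate(dens_all, A)
  est_fia <- design_estimate(dens_fia, A)
  est_bay_sample <- pixel_sample_estimate(bay$mean, clusters, A)
  est_bay_sum <- pixel_sum_estimate(bay)
  truth_raster <- grid_raster(surface$biomass, config$grid)
  est_truth_sum <- pixel_sum_estimate(truth_raster)
  share <- nonforest_share(est_all$total, est_fia$total)
  county <- list(design_all_trees = est_all, design_fia = est_fia,
                 bay_pixel_sample = est_bay_sample, bay_pixel_sum = est_bay_sum,
                 truth_pixel_sum = est_truth_sum,
                 nonforest_share = share,
                 gap_bay_sum_vs_fia = estimate_gap(est_bay_sum, est_fia),
                 gap_bay_sample_vs_all = estimate_gap(est_bay_sample, est_all))
  pipeline_log(verbose, "county",
               "nonforest share %.1f%% (configured %.0f%%); all-tree total %.3f Tg",
               share$nonforest_pct,
               100 * (config$surface$nonforest_biomass_share %||% 0),
               est_all$total)

  report <- structure(
    list(config = config, surface = surface, metrics = metrics,
         clusters = clusters, trees_all = trees_all, trees_fia = trees_fia,
         densities = data.frame(plot_id = ids, all_trees = dens_all,
                                fia = dens_fia),
         allometry = allom, se_functions = se_functions,
         plot_ci = ci_tab, ci_summary = ci_summary,
         spatial_fit = fit, bay = bay, rf = rf, rf_raster = rf_raster,
         comparison = comparison, overlap_fraction = overlap,
         county = county),
    class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== synthetic inter-comparison report ==\n")
  cat(sprintf("landscape: %d x %d pixels; nonforest fraction %.2f\n",
              x$config$grid$n_rows, x$config$grid$n_cols,
              mean(x$surface$condition == "nonforest")))
  cat("\nallometric family means (Mg/ha):\n")
  print(x$allometry$table, row.names = FALSE)
  cat(sprintf("\nplot 95%% CI: mean width %.1f Mg/ha (%.0f%% of plot mean)\n",
              x$ci_summary$mean_width_mgha, x$ci_summary$mean_width_pct_of_mean))
  cb <- x$comparison$bay_all
  cat(sprintf("\nplot vs BAY map: R2 %.2f, slope %.2f, RMSE %.1f Mg/ha, KS %.2f (n=%d)\n",
              cb$r_squared, cb$slope, cb$rmse, cb$ks, cb$n_pairs))
  cat(sprintf("CI overlap fraction: %.2f\n", x$overlap_fraction))
  cat("\ncounty estimates:\n")
  for (nm in c("design_all_trees", "design_fia", "bay_pixel_sample",
               "bay_pixel_sum", "truth_pixel_sum")) {
    cat("  ", nm, ": ", sep = ""); print(x$county[[nm]])
  }
  cat(sprintf("nonforest share: %.3g Tg (%.1f%%)\n",
              x$county$nonforest_share$nonforest_tg,
              x$county$nonforest_share$nonforest_pct))
  invisible(x)
}

county_to_list <- function(est) {
  list(method = est$method, mean_mgha = est$mean, mean_ci = est$mean_ci,
       total_tg = est$total, total_ci = est$total_ci, n = est$n)
}

#' Write pipeline artifacts to a directory
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_tree_table(report$trees_all, p("trees_all.csv"))
  write_tree_table(report$trees_fia, p("trees_fia.csv"))
  write_plot_table(report$clusters, p("plots.csv"))
  utils::write.csv(report$plot_ci, p("plot_ci.csv"), row.names = FALSE)
  write_raster_asc(grid_raster(report$surface$biomass, report$config$grid),
                   p("true_biomass.asc"))
  write_raster_asc(report$bay$mean, p("bay_mean.asc"))
  write_raster_asc(report$bay$lower, p("bay_lo95.asc"))
  write_raster_asc(report$bay$upper, p("bay_hi95.asc"))
  write_raster_asc(report$rf_raster, p("rf_mean.asc"))
  comp <- lapply(report$comparison, function(cs) {
    cs[c("r_squared", "slope", "rmse", "ks", "n_pairs")]
  })
  comp$overlap_fraction <- report$overlap_fraction
  jsonlite::write_json(comp, p("comparison.json"), auto_unbox = TRUE,
                       digits = NA)
  county <- lapply(report$county[c("design_all_trees", "design_fia",
                                   "bay_pixel_sample", "bay_pixel_sum",
                                   "truth_pixel_sum")], county_to_list)
  county$nonforest_share <- report$county$nonforest_share
  jsonlite::write_json(county, p("county.json"), auto_unbox = TRUE,
                       digits = NA)
  summary_txt <- utils::capture.output(print(report))
  writeLines(summary_txt, p("report.txt"))
  invisible(out_dir)
}
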