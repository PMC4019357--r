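TREE_TABLE_COLUMNS <- c("plot_id", "subplot_id", "condition",
                        "species_group", "dbh_cm", "bole_height_m")

check_tree_table <- function(trees, require_height = FALSE) {
  need <- TREE_TABLE_COLUMNS
  if (!require_height) need <- setdiff(need, "bole_height_m")
  missing <- setdiff(need, names(trees))
  if (length(missing)) {
    stop("tree table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(trees)
}

#' Read and write tree-record tables
#'
#' One row per measured stem with columns `plot_id`, `subplot_id`,
#' `condition` (`"forest"`/`"nonforest"`), `species_group`, `dbh_cm`,
#' `bole_height_m` (plus any extras, which round-trip untouched). Missing
#' required columns raise a named-column error.
#'
#' @param trees tree-record data.frame.
#' @param path CSV file path.
#' @return `read_tree_table` returns the validated data.frame.
#' @export
write_tree_table <- function(trees, path) {
  check_tree_table(trees)
  utils::write.csv(trees, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_table
#' @export
read_tree_table <- function(path) {
  trees <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_tree_table(trees)
  trees
}

#' Read and write plot-location tables
#'
#' One row per subplot center: `plot_id`, `subplot_id`, `x`, `y`, `mode`,
#' `subplot_area_m2`. Coordinates are in the projected CRS of the grid
#' (meters).
#'
#' @param clusters list of plot clusters (see [generate_plot_network()]).
#' @param path CSV file path.
#' @return `read_plot_table` returns a list of `plot_cluster` objects.
#' @export
write_plot_table <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(plot_id = cl$plot_id,
               subplot_id = seq_len(nrow(cl$centers)),
               x = cl$centers[, 1], y = cl$centers[, 2],
               mode = cl$mode, subplot_area_m2 = cl$subplot_area)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "subplot_id", "x", "y", "mode", "subplot_area_m2")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    stop("plot table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(rows, rows$plot_id), function(r) {
    r <- r[order(r$subplot_id), ]
    plot_cluster(plot_id = r$plot_id[1],
                 centers = cbind(r$x, r$y),
                 mode = r$mode[1],
                 subplot_area = r$subplot_area_m2[1])
  })
}
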