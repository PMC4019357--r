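#' Define a north-up raster grid
#'
#' A `grid_spec` describes a regular, north-up raster grid in a projected
#' coordinate system with units of meters. `origin` is the lower-left corner
#' of the grid (the outer corner of the bottom-left pixel). Rows are counted
#' from the top of the grid downwards, matching the on-disk row order of
#' raster formats.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pixel_size pixel edge length in meters (default 30, the working
#'   resolution of most regional canopy-metric products).
#' @param origin numeric length-2: x/y coordinate of the lower-left corner.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 30, origin = c(0, 0)) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be single integers >= 1", call. = FALSE)
  }
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("origin must be a finite numeric vector of length 2", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = as.numeric(pixel_size), origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.6g m, origin (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$n_cols * grid$pixel_size,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + grid$n_rows * grid$pixel_size)
}

#' Pixel center coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `row`, `col`, `x`, `y`, in row-major order
#'   (row 1 = northernmost row).
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  px <- grid$pixel_size
  ytop <- grid$origin[2] + grid$n_rows * px
  g <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  data.frame(
    row = g$row, col = g$col,
    x = grid$origin[1] + (g$col - 0.5) * px,
    y = ytop - (g$row - 0.5) * px
  )
}

#' Locate the pixel containing a point
#'
#' Pixel membership uses the half-open convention `[x, x + s)` horizontally
#' and `(y - s, y]` vertically (north-up), so a point on a shared boundary is
#' assigned to exactly one pixel and the assignment is deterministic.
#'
#' @param grid a [grid_spec()].
#' @param x,y point coordinates (vectorized).
#' @return data.frame with columns `row`, `col`; out-of-extent points raise an
#'   error.
#' @export
locate_pixel <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  px <- grid$pixel_size
  ytop <- grid$origin[2] + grid$n_rows * px
  col <- floor((x - grid$origin[1]) / px) + 1
  row <- floor((ytop - y) / px) + 1
  # top edge of the grid is closed; everything else follows the half-open rule
  row[y == ytop] <- 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad)) {
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)),
         call. = FALSE)
  }
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Construct a single-band raster on a grid
#'
#' @param values numeric matrix of dimension `n_rows x n_cols` (row 1 = top).
#' @param grid a [grid_spec()].
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("values matrix does not match the grid dimensions", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_raster> %d x %d @ %.6g m; range [%.4g, %.4g], %d NA\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange: the six-line ESRI ASCII header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' from north to south. Round-trips the cell values, grid dimensions,
#' geotransform and no-data cells exactly (values are written with full
#' double precision).
#'
#' @param raster a [grid_raster()].
#' @param path file path.
#' @return `write_raster_asc` returns `path` invisibly; `read_raster_asc`
#'   returns a [grid_raster()].
#' @export
write_raster_asc <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  g <- raster$grid
  v <- raster$values
  nodata <- -9999
  if (any(is.finite(v) & v == nodata)) {
    stop("raster contains the reserved no-data value -9999", call. = FALSE)
  }
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$pixel_size),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (length(ln) != 1L) stop("malformed ASCII grid header: ", key, call. = FALSE)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  if (length(body) != nrows) stop("ASCII grid body has wrong row count", call. = FALSE)
  v <- t(vapply(body, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(ncols), USE.NAMES = FALSE))
  v[v == nodata] <- NA_real_
  grid_raster(v, grid_spec(nrows, ncols, cs, c(xll, yll)))
}
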