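#' Grid specification for a square-pixel raster
#'
#' A `grid_spec` describes the georeferencing of a raster: the map coordinate
#' of the grid's north-west corner, a single (square) pixel size in meters,
#' and the grid dimensions. Row 1 is the northernmost row; cells are addressed
#' `(row, col)` and a cell's value represents conditions at its center.
#'
#' @param x_origin Map x-coordinate (m) of the western edge of the grid.
#' @param y_origin Map y-coordinate (m) of the northern edge of the grid.
#' @param pixel_size Side length of a (square) pixel, in meters. Must be > 0.
#' @param n_rows,n_cols Grid dimensions; both must be >= 1.
#' @param crs_id Free-text identifier of the projected coordinate reference
#'   system. The package performs no reprojection; all layers of an analysis
#'   must share one planar CRS in meters.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 9000, 90, 100, 100)
#' cell_centers(g)[1, ]
#' @export
grid_spec <- function(x_origin, y_origin, pixel_size, n_rows, n_cols,
                      crs_id = "local-m") {
  stopifnot(is.numeric(x_origin), is.numeric(y_origin))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (square pixels)")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("n_rows and n_cols must be >= 1")
  }
  structure(
    list(
      x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
      pixel_size = as.numeric(pixel_size),
      n_rows = n_rows, n_cols = n_cols, crs_id = crs_id
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells @ %g m, NW corner (%g, %g), crs '%s'\n",
    x$n_rows, x$n_cols, x$pixel_size, x$x_origin, x$y_origin, x$crs_id
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$pixel_size)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$x_origin - b$x_origin) <= tol &&
    abs(a$y_origin - b$y_origin) <= tol &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Map coordinates of all cell centers
#'
#' @param grid A [grid_spec()].
#' @return A matrix with columns `x`, `y`, one row per cell in row-major
#'   (northernmost row first) order.
#' @export
cell_centers <- function(grid) {
  px <- grid$pixel_size
  xs <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * px
  ys <- grid$y_origin - (seq_len(grid$n_rows) - 0.5) * px
  cbind(x = rep(xs, times = grid$n_rows), y = rep(ys, each = grid$n_cols))
}

# column-major centers matching as.vector(values); cheaper layout internally
cell_centers_colmajor <- function(grid) {
  px <- grid$pixel_size
  xs <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * px
  ys <- grid$y_origin - (seq_len(grid$n_rows) - 0.5) * px
  list(x = rep(xs, each = grid$n_rows), y = rep(ys, times = grid$n_cols))
}

#' Construct a raster
#'
#' The package-wide raster container: a numeric matrix of cell values plus a
#' [grid_spec()]. Missing cells are held as `NA` in memory; `nodata` is the
#' sentinel used on disk. `NA` cells are excluded from every statistic the
#' package computes, never silently averaged in.
#'
#' @param values Numeric matrix, `n_rows x n_cols`, row 1 = northernmost.
#' @param grid A [grid_spec()]; its dimensions must match `values`.
#' @param nodata Sentinel value used when writing to disk (default -9999).
#' @return An object of class `lii_raster`.
#' @examples
#' r <- lii_raster(matrix(runif(9), 3, 3), grid_spec(0, 270, 90, 3, 3))
#' raster_values(r)[1, 1]
#' @export
lii_raster <- function(values, grid, nodata = -9999) {
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf(
      "values shape (%d x %d) does not match grid (%d x %d)",
      nrow(values), ncol(values), grid$n_rows, grid$n_cols
    ))
  }
  structure(list(values = values, grid = grid, nodata = nodata),
            class = "lii_raster")
}

#' @export
print.lii_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  rng <- if (length(v)) sprintf("[%.4g, %.4g]", min(v), max(v)) else "(all nodata)"
  cat(sprintf(
    "<lii_raster> %s, values %s, %d nodata cell(s)\n",
    format(x$grid), rng, sum(is.na(x$values))
  ))
  invisible(x)
}

#' Extract the value matrix of a raster
#' @param r An [lii_raster()].
#' @return The numeric value matrix (`NA` = nodata).
#' @export
raster_values <- function(r) {
  stopifnot(inherits(r, "lii_raster"))
  r$values
}

# replace values, keep grid/nodata
with_values <- function(r, values) lii_raster(values, r$grid, r$nodata)

#' Convert a raster to a tibble of cell centers
#'
#' One row per cell with map coordinates, grid indices and value; nodata cells
#' carry `NA`. Useful for dplyr summaries and ggplot2.
#'
#' @param x An [lii_raster()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `row`, `col`, `value`.
#' @export
as_tibble.lii_raster <- function(x, ...) {
  cc <- cell_centers_colmajor(x$grid)
  tibble::tibble(
    x = cc$x, y = cc$y,
    row = rep(seq_len(x$grid$n_rows), x$grid$n_cols),
    col = rep(seq_len(x$grid$n_cols), each = x$grid$n_rows),
    value = as.vector(x$values)
  )
}

#' Plot a raster with ggplot2
#'
#' @param object An [lii_raster()].
#' @param name Legend title.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lii_raster <- function(object, name = "value", ...) {
  df <- as_tibble.lii_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' @export
plot.lii_raster <- function(x, ...) print(autoplot.lii_raster(x, ...))

# assert every layer shares one grid
check_shared_grid <- function(rasters) {
  if (length(rasters) < 1) stop("empty raster list")
  g <- rasters[[1]]$grid
  for (r in rasters[-1]) {
    if (!same_grid(g, r$grid)) stop("grid mismatch between input rasters")
  }
  g
}
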