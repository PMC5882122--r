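#' Rasterize a feature collection to a binary presence grid
#'
#' A cell is marked 1 when it is intersected by any feature: points mark the
#' cell containing them, lines mark every cell whose (closed) square the line
#' touches, and polygons mark cells whose center falls inside the polygon
#' (even-odd rule, holes supported). All other cells are 0. An empty
#' collection yields an all-zero raster with a warning, not an error — an
#' area can legitimately lack a given land use.
#'
#' @param features An [lii_features()] collection (same planar CRS as `grid`).
#' @param grid Target [grid_spec()].
#' @return Binary [lii_raster()] of 0/1 presence.
#' @export
rasterize_features <- function(features, grid) {
  stopifnot(inherits(features, "lii_features"), inherits(grid, "grid_spec"))
  m <- matrix(0, grid$n_rows, grid$n_cols)
  if (!length(features$geoms)) {
    warning("empty feature collection: rasterized to all-zero presence")
    return(lii_raster(m, grid))
  }
  px <- grid$pixel_size
  x0 <- grid$x_origin
  y0 <- grid$y_origin
  # cell (r, c) spans x in [x0+(c-1)px, x0+c*px], y in [y0-r*px, y0-(r-1)px]
  for (i in seq_along(features$geoms)) {
    g <- features$geoms[[i]]
    switch(features$types[i],
      point = {
        cc <- point_cell(g[1], g[2], grid)
        if (!is.null(cc)) m[cc[1], cc[2]] <- 1
      },
      line = {
        for (s in seq_len(nrow(g) - 1)) {
          hits <- segment_cells(g[s, ], g[s + 1, ], grid)
          if (nrow(hits)) m[hits] <- 1
        }
      },
      polygon = {
        cen <- cell_centers_colmajor(grid)
        inside <- rep(FALSE, length(cen$x))
        for (ring in g) inside <- xor(inside, ring_contains(cen$x, cen$y, ring))
        m[matrix(inside, grid$n_rows, grid$n_cols)] <- 1
      }
    )
  }
  lii_raster(m, grid)
}

# cell index of a point, NULL when outside the grid extent
point_cell <- function(x, y, grid) {
  px <- grid$pixel_size
  col <- floor((x - grid$x_origin) / px) + 1
  row <- floor((grid$y_origin - y) / px) + 1
  # points exactly on the east/south outer edge belong to the last cell
  if (col == grid$n_cols + 1 && x == grid$x_origin + grid$n_cols * px) col <- grid$n_cols
  if (row == grid$n_rows + 1 && y == grid$y_origin - grid$n_rows * px) row <- grid$n_rows
  if (col < 1 || col > grid$n_cols || row < 1 || row > grid$n_rows) return(NULL)
  c(row, col)
}

# cells whose closed square a segment touches (Liang-Barsky clip per cell,
# restricted to the segment's bounding box)
segment_cells <- function(p, q, grid) {
  px <- grid$pixel_size
  c_lo <- max(1L, floor((min(p[1], q[1]) - grid$x_origin) / px) + 1L)
  c_hi <- min(grid$n_cols, floor((max(p[1], q[1]) - grid$x_origin) / px) + 1L)
  r_lo <- max(1L, floor((grid$y_origin - max(p[2], q[2])) / px) + 1L)
  r_hi <- min(grid$n_rows, floor((grid$y_origin - min(p[2], q[2])) / px) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(matrix(integer(), 0, 2))
  out <- matrix(integer(), 0, 2)
  for (r in r_lo:r_hi) {
    ymax <- grid$y_origin - (r - 1) * px
    ymin <- ymax - px
    for (cc in c_lo:c_hi) {
      xmin <- grid$x_origin + (cc - 1) * px
      if (segment_hits_box(p, q, xmin, xmin + px, ymin, ymax)) {
        out <- rbind(out, c(r, cc))
      }
    }
  }
  out
}

# does segment p->q intersect the closed axis-aligned box?
segment_hits_box <- function(p, q, xmin, xmax, ymin, ymax) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- if (k == 1) xmin else ymin
    hi <- if (k == 1) xmax else ymax
    if (d[k] == 0) {
      if (p[k] < lo || p[k] > hi) return(FALSE)
    } else {
      ta <- (lo - p[k]) / d[k]
      tb <- (hi - p[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta)
      t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# even-odd ray cast of many points against one ring (vectorized over points)
ring_contains <- function(xs, ys, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (yi != yj) {
      cross <- ((yi > ys) != (yj > ys)) &
        (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Resample a raster onto a new grid
#'
#' `nearest` picks the source cell containing each target cell center (use for
#' categorical or binary data); `bilinear` interpolates the four surrounding
#' source cell centers (use for continuous data). Both methods keep output
#' values within the source value range. Target cells outside the source
#' extent are nodata; fully disjoint extents are an error.
#'
#' @param r Source [lii_raster()].
#' @param target Target [grid_spec()].
#' @param method `"nearest"` or `"bilinear"`.
#' @return An [lii_raster()] on `target`.
#' @export
resample <- function(r, target, method = c("nearest", "bilinear")) {
  stopifnot(inherits(r, "lii_raster"), inherits(target, "grid_spec"))
  method <- match.arg(method)
  sg <- r$grid
  s_xmax <- sg$x_origin + sg$n_cols * sg$pixel_size
  s_ymin <- sg$y_origin - sg$n_rows * sg$pixel_size
  t_xmax <- target$x_origin + target$n_cols * target$pixel_size
  t_ymin <- target$y_origin - target$n_rows * target$pixel_size
  if (target$x_origin >= s_xmax || t_xmax <= sg$x_origin ||
      target$y_origin <= s_ymin || t_ymin >= sg$y_origin) {
    stop("disjoint extents: source and target rasters do not overlap")
  }
  if (same_grid(sg, target)) return(lii_raster(r$values, target, r$nodata))
  cen <- cell_centers_colmajor(target)
  px <- sg$pixel_size
  if (method == "bilinear" && (sg$n_rows < 2 || sg$n_cols < 2)) {
    method <- "nearest"  # a 1-cell-wide source has no interpolation neighbors
  }
  if (method == "nearest") {
    col <- floor((cen$x - sg$x_origin) / px) + 1
    row <- floor((sg$y_origin - cen$y) / px) + 1
    ok <- col >= 1 & col <= sg$n_cols & row >= 1 & row <= sg$n_rows
    v <- rep(NA_real_, length(col))
    v[ok] <- r$values[cbind(row[ok], col[ok])]
  } else {
    # continuous 0-based index in source cell-center space
    gx <- (cen$x - (sg$x_origin + 0.5 * px)) / px
    gy <- ((sg$y_origin - 0.5 * px) - cen$y) / px
    ok <- gx > -0.5 & gx < sg$n_cols - 0.5 & gy > -0.5 & gy < sg$n_rows - 0.5
    gx <- pmin(pmax(gx, 0), sg$n_cols - 1)
    gy <- pmin(pmax(gy, 0), sg$n_rows - 1)
    cx0 <- pmin(floor(gx), sg$n_cols - 2); cx0 <- pmax(cx0, 0)
    cy0 <- pmin(floor(gy), sg$n_rows - 2); cy0 <- pmax(cy0, 0)
    fx <- gx - cx0
    fy <- gy - cy0
    v00 <- r$values[cbind(cy0 + 1, cx0 + 1)]
    v01 <- r$values[cbind(cy0 + 1, cx0 + 2)]
    v10 <- r$values[cbind(cy0 + 2, cx0 + 1)]
    v11 <- r$values[cbind(cy0 + 2, cx0 + 2)]
    w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
    w10 <- (1 - fx) * fy;       w11 <- fx * fy
    num <- rowSums(cbind(w00 * v00, w01 * v01, w10 * v10, w11 * v11),
                   na.rm = TRUE)
    den <- rowSums(cbind(w00 * !is.na(v00), w01 * !is.na(v01),
                         w10 * !is.na(v10), w11 * !is.na(v11)))
    v <- ifelse(den > 0 & ok, num / den, NA_real_)
  }
  lii_raster(matrix(v, target$n_rows, target$n_cols), target, r$nodata)
}
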