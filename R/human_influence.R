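#' Distance-decay intactness curve
#'
#' Maps distance-to-feature (m) to an intactness value in `[s, 1]`, where `s`
#' is the layer's site impact score. Both families satisfy `curve(0) = s`,
#' `curve(d) = 1` for all `d >= D` (the distance of influence), and are
#' monotone non-decreasing:
#'
#' * `linear`: `s + (1 - s) * min(d, D) / D`.
#' * `logistic`: a symmetric S-curve. The raw curve
#'   `f(d) = 1 / (1 + exp(-k (d - D/2)))` uses slope `k = 2 ln((1-eps)/eps)/D`
#'   so that `f(0) = eps` and `f(D) = 1 - eps`; it is then affinely rescaled
#'   from `[eps, 1-eps]` to `[s, 1]` so the published endpoints are hit
#'   exactly, and clamped to 1 beyond `D`. At the midpoint `D/2` the value is
#'   exactly `(s + 1)/2`.
#'
#' @param params A [decay_params()] triple.
#' @param epsilon Raw-logistic tail tolerance at the endpoints (default 0.01);
#'   only the logistic family uses it.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(params, epsilon = 0.01) {
  stopifnot(inherits(params, "decay_params"))
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must be in (0, 0.5)")
  }
  structure(list(params = params, epsilon = epsilon), class = "decay_curve")
}

#' Evaluate a distance-decay curve
#'
#' @param d Distances in meters (vectorized); must be >= 0. `Inf` is allowed
#'   and maps to intactness 1 (no feature anywhere).
#' @param curve A [decay_curve()].
#' @return Intactness values in `[site_impact, 1]`.
#' @examples
#' cv <- decay_curve(decay_params(0.75, 500, "linear"))
#' decay_value(c(0, 250, 500, 1e4), cv)
#' @export
decay_value <- function(d, curve) {
  stopifnot(inherits(curve, "decay_curve"))
  if (any(d < 0, na.rm = TRUE)) stop("negative distance")
  s <- curve$params$site_impact
  D <- curve$params$distance_m
  out <- rep(NA_real_, length(d))
  ok <- !is.na(d)
  di <- pmin(d[ok], D)
  if (curve$params$family == "linear") {
    v <- s + (1 - s) * di / D
  } else {
    eps <- curve$epsilon
    k <- 2 * log((1 - eps) / eps) / D
    f <- 1 / (1 + exp(-k * (di - D / 2)))
    v <- s + (1 - s) * (f - eps) / (1 - 2 * eps)
  }
  # endpoints are exact by construction of the rescaling, not by floating
  # arithmetic: pin them so curve(0) == s and curve(d >= D) == 1 identically
  v[d[ok] == 0] <- s
  v[d[ok] >= D] <- 1
  out[ok] <- pmin(pmax(v, s), 1)
  out
}

#' Euclidean distance to the nearest presence cell
#'
#' For each cell, the straight-line distance (m) from its center to the center
#' of the nearest cell with presence 1; presence cells hold 0. Computed with
#' the exact two-pass separable squared-distance transform (lower-envelope of
#' parabolas), so results equal the brute-force all-pairs search. With no
#' presence cells anywhere, every cell is `Inf` (downstream decay maps this to
#' full intactness). Nodata cells are treated as absence for the transform but
#' re-propagated as nodata in the output.
#'
#' @param presence Binary [lii_raster()] (values 0/1, `NA` allowed).
#' @return An [lii_raster()] of distances in meters.
#' @export
euclidean_distance <- function(presence) {
  stopifnot(inherits(presence, "lii_raster"))
  m <- presence$values
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("presence raster must be binary {0,1}")
  }
  nr <- nrow(m); nc <- ncol(m)
  pres <- !is.na(m) & m == 1
  # phase 1: per column, squared row-distance to nearest presence in column
  g <- matrix(Inf, nr, nc)
  for (cc in seq_len(nc)) {
    rows <- which(pres[, cc])
    if (!length(rows)) next
    d <- rep(Inf, nr)
    d[rows] <- 0
    if (nr > 1) {
      for (r in 2:nr) d[r] <- min(d[r], d[r - 1] + 1)
      for (r in (nr - 1):1) d[r] <- min(d[r], d[r + 1] + 1)
    }
    g[, cc] <- d^2
  }
  # phase 2: per row, lower envelope across columns
  d2 <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) {
    d2[r, ] <- dt1d_squared(g[r, ])
  }
  out <- sqrt(d2) * presence$grid$pixel_size
  out[is.na(m)] <- NA_real_
  with_values(presence, out)
}

# 1-D squared distance transform of sampled function f (Inf allowed):
# result[q] = min_p (q - p)^2 + f[p]   (Felzenszwalb & Huttenlocher)
dt1d_squared <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(rep(Inf, n))
  v <- integer(length(fin)); z <- numeric(length(fin) + 1)
  k <- 1
  v[1] <- fin[1]
  z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      if (s <= z[k]) k <- k - 1 else break
    }
    k <- k + 1
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  d <- numeric(n)
  k <- 1
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Per-layer human-influence intactness surface
#'
#' Applies a layer's distance-decay curve cellwise to the Euclidean distance
#' surface of its presence raster. Values lie in `[site_impact, 1]`: exactly
#' the site impact score on the features and exactly 1 at or beyond the
#' distance of influence.
#'
#' @param presence Binary [lii_raster()] on the model grid.
#' @param curve A [decay_curve()].
#' @return An [lii_raster()] of intactness in `[s, 1]`.
#' @export
layer_hii <- function(presence, curve) {
  d <- euclidean_distance(presence)
  v <- decay_value(as.vector(d$values), curve)
  with_values(presence, matrix(v, nrow(d$values), ncol(d$values)))
}

#' Composite human influence: cellwise minimum across layers
#'
#' The composite records, at each cell, the most impacted (lowest intactness)
#' of all per-layer surfaces. Nodata in any layer propagates to the output.
#'
#' @param layers Non-empty list of [lii_raster()]s on one grid.
#' @return An [lii_raster()]; everywhere `<=` each input.
#' @export
composite_hii <- function(layers) {
  g <- check_shared_grid(layers)
  out <- layers[[1]]$values
  for (r in layers[-1]) out <- pmin(out, r$values)  # pmin(NA, x) is NA
  lii_raster(out, g, layers[[1]]$nodata)
}

#' Build the full Human Influence Index from features and a configuration
#'
#' Rasterizes each configured layer's features to presence, computes its
#' Euclidean distance surface, applies its decay curve, and composites the
#' per-layer intactness surfaces with a cellwise minimum.
#'
#' @param features_by_layer Named list of [lii_features()] (or presence
#'   [lii_raster()]s for `raster_mask` layers), keyed by layer name. Layers
#'   missing from the list are treated as empty (full intactness).
#' @param config Layer configuration from [load_layer_config()] /
#'   [default_layer_config()].
#' @param grid Model [grid_spec()] (the 90-m grid).
#' @param epsilon Logistic tail tolerance, see [decay_curve()].
#' @return List with `hii` (composite [lii_raster()]) and `layers` (named list
#'   of per-layer intactness rasters).
#' @export
build_hii <- function(features_by_layer, config, grid, epsilon = 0.01) {
  per_layer <- list()
  for (lc in config) {
    src <- features_by_layer[[lc$name]]
    if (is.null(src)) src <- lii_features()
    presence <- if (inherits(src, "lii_raster")) {
      resample(src, grid, "nearest")
    } else {
      withCallingHandlers(
        rasterize_features(src, grid),
        warning = function(w) {
          if (grepl("empty feature collection", conditionMessage(w))) {
            invokeRestart("muffleWarning")  # absence of a land use is expected
          }
        }
      )
    }
    per_layer[[lc$name]] <- layer_hii(presence, decay_curve(lc$decay, epsilon))
  }
  list(hii = composite_hii(per_layer), layers = per_layer)
}
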