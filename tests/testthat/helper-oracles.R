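# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: all-pairs search instead of the separable distance transform,
# nested window loops instead of shifted accumulation, array Dijkstra instead
# of the igraph lattice, segment-segment tests instead of Liang-Barsky.

make_grid <- function(n_rows, n_cols, px = 90) {
  grid_spec(0, n_rows * px, px, n_rows, n_cols)
}

make_raster <- function(values, px = 90) {
  values <- as.matrix(values)
  lii_raster(values, make_grid(nrow(values), ncol(values), px))
}

# all-pairs nearest-presence squared distance, in pixel units
oracle_edt_sq <- function(pres) {
  nr <- nrow(pres); nc <- ncol(pres)
  ps <- which(pres == 1, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (!nrow(ps)) return(out)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- min((ps[, 1] - r)^2 + (ps[, 2] - c)^2)
  }
  out
}

# nested-loop circular-window mean, NA-aware
oracle_focal <- function(m, radius, px) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (((rr - r)^2 + (cc - c)^2) * px^2 <= radius^2 * (1 + 1e-12) &&
          !is.na(m[rr, cc])) {
        acc <- acc + m[rr, cc]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) out[r, c] <- acc / cnt
  }
  out
}

# array-scan Dijkstra over the 8-connected lattice
oracle_cost_distance <- function(res, src) {
  nr <- nrow(res); nc <- ncol(res); n <- nr * nc
  dist <- rep(Inf, n)
  dist[which(src)] <- 0
  done <- rep(FALSE, n)
  repeat {
    d <- ifelse(done, Inf, dist)
    u <- which.min(d)
    if (is.infinite(d[u])) break
    done[u] <- TRUE
    r <- (u - 1) %% nr + 1; c <- (u - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- (cc - 1) * nr + rr
      w <- (res[u] + res[v]) / 2 * sqrt(dr^2 + dc^2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc)
}

# segment-vs-cell-square intersection built from orientation tests
seg_seg_intersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
    (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

oracle_segment_touches_cell <- function(p, q, xmin, xmax, ymin, ymax) {
  inside <- function(pt) {
    pt[1] >= xmin && pt[1] <= xmax && pt[2] >= ymin && pt[2] <= ymax
  }
  if (inside(p) || inside(q)) return(TRUE)
  corners <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (e in edges) {
    if (seg_seg_intersect(p, q, corners[[e[1]]], corners[[e[2]]])) return(TRUE)
  }
  FALSE
}

# 8-connected flood fill from seed cells, restricted to mask
oracle_flood_fill <- function(mask, seeds) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- which(seeds & mask)
  reach[queue] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    r <- (u - 1) %% nr + 1; c <- (u - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- (cc - 1) * nr + rr
      if (mask[v] && !reach[v]) {
        reach[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  reach
}

# published 16-layer parameterization (name -> impact, distance, family)
published_layer_params <- function() {
  tibble::tribble(
    ~name, ~site_impact, ~distance_m, ~decay,
    "primitive_roads", 0.75, 500, "linear",
    "local_roads", 0.3, 1500, "logistic",
    "major_highways", 0.015, 4000, "logistic",
    "low_density_development", 0.6, 1000, "logistic",
    "medium_density_development", 0.35, 2000, "logistic",
    "high_density_development", 0.015, 4000, "logistic",
    "communication_towers", 0.6, 200, "linear",
    "powerlines", 0.6, 200, "linear",
    "mines_and_well_pads", 0.2, 1000, "logistic",
    "urban_polygons", 0.015, 4000, "logistic",
    "high_impervious_surfaces", 0.3, 1000, "logistic",
    "low_agriculture_and_invasives", 0.7, 500, "linear",
    "pasture", 0.7, 500, "linear",
    "grazing_allotments", 0.7, 500, "linear",
    "introduced_vegetation", 0.6, 500, "linear",
    "cultivated_agriculture", 0.35, 2000, "linear"
  )
}
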