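#' Resistance surface from a landscape-integrity surface
#'
#' Corridors should follow the paths of highest integrity, so movement
#' resistance decreases with the index: `resistance = max(1 - LII, floor)`.
#' The floor keeps resistance strictly positive where integrity is perfect.
#' `literal = TRUE` instead uses the index itself as resistance (routing
#' through degraded land), kept for comparison.
#'
#' @param lii An `lii_surface` (or [lii_raster()] of index values in
#'   `[0, 1]`).
#' @param floor Minimum resistance (default 1e-6).
#' @param literal Use the index directly as resistance.
#' @return An [lii_raster()] of strictly positive resistances.
#' @export
resistance_from_lii <- function(lii, floor = 1e-6, literal = FALSE) {
  r <- if (inherits(lii, "lii_surface")) lii$values else lii
  stopifnot(inherits(r, "lii_raster"), floor > 0)
  v <- if (literal) r$values else 1 - r$values
  with_values(r, pmax(v, floor))
}

#' Accumulated least-cost distance from source cells
#'
#' Minimum accumulated cost over 8-connected paths from any source cell. The
#' cost of a move between adjacent cells is the mean of the two cell
#' resistances times the center-to-center distance in pixel units (1
#' orthogonal, sqrt(2) diagonal). Source cells cost 0; valid cells unreachable
#' from any source are `Inf`; nodata stays nodata. Implemented as Dijkstra's
#' algorithm on the explicit lattice graph (via igraph) with a zero-weight
#' virtual vertex tied to all sources.
#'
#' @param resistance [lii_raster()], strictly positive on valid cells.
#' @param sources Binary [lii_raster()] of source cells on the same grid.
#' @return [lii_raster()] of accumulated costs.
#' @export
cost_distance <- function(resistance, sources) {
  stopifnot(inherits(resistance, "lii_raster"), inherits(sources, "lii_raster"))
  if (!same_grid(resistance$grid, sources$grid)) stop("grid mismatch")
  res <- resistance$values
  if (any(res <= 0, na.rm = TRUE)) stop("nonpositive resistance")
  src <- !is.na(sources$values) & sources$values == 1 & !is.na(res)
  if (!any(src)) stop("no source cells")
  nr <- nrow(res); nc <- ncol(res)
  valid <- !is.na(res)
  idx <- matrix(NA_integer_, nr, nc)
  idx[valid] <- seq_len(sum(valid))
  n_valid <- sum(valid)
  edges <- lattice_edges(idx, res, nr, nc)
  # virtual source vertex n_valid + 1 at zero cost to every source cell
  src_ids <- idx[src]
  el <- rbind(edges$el, cbind(rep(n_valid + 1L, length(src_ids)), src_ids))
  w <- c(edges$w, rep(0, length(src_ids)))
  gph <- igraph::make_empty_graph(n = n_valid + 1L, directed = FALSE)
  gph <- igraph::add_edges(gph, t(el))
  d <- igraph::distances(gph, v = n_valid + 1L, weights = w,
                         algorithm = "dijkstra")[1, seq_len(n_valid)]
  out <- matrix(NA_real_, nr, nc)
  out[valid] <- d
  with_values(resistance, out)
}

# 8-neighbor edge list over valid cells: east, south, south-east, south-west
lattice_edges <- function(idx, res, nr, nc) {
  el <- list(); w <- list(); k <- 0
  add <- function(r1, c1, r2, c2, dist) {
    a <- idx[cbind(r1, c1)]; b <- idx[cbind(r2, c2)]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    k <<- k + 1
    el[[k]] <<- cbind(a[ok], b[ok])
    w[[k]] <<- (res[cbind(r1, c1)][ok] + res[cbind(r2, c2)][ok]) / 2 * dist
  }
  rs <- rep(seq_len(nr), nc - 1); cs <- rep(seq_len(nc - 1), each = nr)
  add(rs, cs, rs, cs + 1, 1)                     # east
  rs <- rep(seq_len(nr - 1), nc); cs <- rep(seq_len(nc), each = nr - 1)
  add(rs, cs, rs + 1, cs, 1)                     # south
  rs <- rep(seq_len(nr - 1), nc - 1); cs <- rep(seq_len(nc - 1), each = nr - 1)
  add(rs, cs, rs + 1, cs + 1, sqrt(2))           # south-east
  add(rs, cs + 1, rs + 1, cs, sqrt(2))           # south-west
  list(el = do.call(rbind, el), w = unlist(w))
}

#' Corridor-value surface for a pair of endpoint areas
#'
#' `cost_a + cost_b`, shifted so the minimum over valid cells is 0: zero along
#' the least-cost path linking the two areas, small within the corridor swath.
#'
#' @param cost_a,cost_b Accumulated-cost [lii_raster()]s from the two
#'   endpoints (see [cost_distance()]), on one grid.
#' @return [lii_raster()] of corridor values >= 0.
#' @export
corridor_surface <- function(cost_a, cost_b) {
  stopifnot(inherits(cost_a, "lii_raster"), inherits(cost_b, "lii_raster"))
  if (!same_grid(cost_a$grid, cost_b$grid)) stop("grid mismatch")
  tot <- cost_a$values + cost_b$values
  fin <- tot[is.finite(tot)]
  if (!length(fin)) stop("no finite corridor values (endpoints not connected)")
  with_values(cost_a, tot - min(fin))
}

#' Select the corridor network covering a fraction of unprotected land
#'
#' Takes the cellwise best (minimum) corridor value across all endpoint
#' pairs, then selects the best-ranked cells outside the priority areas until
#' the requested fraction of valid non-priority land is covered ("highest
#' value" = closest to the least-cost optimum). Ties at the selection
#' boundary break deterministically in row-major cell order.
#'
#' @param corridors Non-empty list of corridor-value [lii_raster()]s (one per
#'   pair, see [corridor_surface()]).
#' @param priority_mask Binary [lii_raster()]: 1 inside priority areas.
#' @param fraction Fraction of valid non-priority cells to select, in (0, 1)
#'   (default 0.30).
#' @return Binary [lii_raster()] corridor-network mask, with the combined
#'   minimum corridor-value surface attached as attribute `combined`.
#' @export
select_corridors <- function(corridors, priority_mask, fraction = 0.30) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  g <- check_shared_grid(c(corridors, list(priority_mask)))
  best <- corridors[[1]]$values
  for (r in corridors[-1]) best <- pmin(best, r$values)
  outside <- (is.na(priority_mask$values) | priority_mask$values != 1) &
    !is.na(best) & is.finite(best)
  n_out <- sum(outside)
  if (n_out == 0) stop("no valid non-priority cells")
  k <- round(fraction * n_out)
  sel <- matrix(0, g$n_rows, g$n_cols)
  if (k > 0) {
    cand <- which(outside)                        # column-major cell ids
    rm_order <- order(best[cand],
                      (cand - 1) %% g$n_rows * g$n_cols + (cand - 1) %/% g$n_rows)
    sel[cand[rm_order[seq_len(k)]]] <- 1
  }
  sel[is.na(best)] <- NA_real_
  out <- lii_raster(sel, g)
  attr(out, "combined") <- lii_raster(best, g)
  out
}

#' Priority-adjacent high-integrity expansion areas
#'
#' Cells with index values above `threshold` outside the priority areas are
#' grouped into 8-connected components; only components touching the priority
#' mask (edge or corner adjacency, directly or through the component) are
#' retained as candidate protected-area expansions.
#'
#' @param lii An `lii_surface` or [lii_raster()].
#' @param priority_mask Binary [lii_raster()] of current priority areas.
#' @param threshold Index cutoff in (0, 1) (default 0.70, the upper-30%
#'   integrity threshold).
#' @return An object of class `expansion_result`: list with `mask` (binary
#'   raster of retained cells), `components` (tibble: id, n_cells, area_km2,
#'   adjacent), `total_area_km2` and `threshold`.
#' @export
expansion_areas <- function(lii, priority_mask, threshold = 0.70) {
  r <- if (inherits(lii, "lii_surface")) lii$values else lii
  stopifnot(inherits(r, "lii_raster"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!same_grid(r$grid, priority_mask$grid)) stop("grid mismatch")
  g <- r$grid
  pri <- !is.na(priority_mask$values) & priority_mask$values == 1
  high <- !is.na(r$values) & r$values > threshold & !pri
  lab <- label_components(high)
  # adjacency: a component touches the priority mask if any of its cells has
  # an 8-neighbor priority cell
  near_pri <- dilate8(pri)
  touching <- sort(unique(lab[high & near_pri]))
  touching <- touching[touching > 0]
  keep <- matrix(lab %in% touching, nrow(lab), ncol(lab)) & high
  cell_km2 <- (g$pixel_size / 1000)^2
  comp <- if (length(touching)) {
    tibble::tibble(
      id = touching,
      n_cells = vapply(touching, function(ci) sum(lab == ci & high), integer(1))
    )
  } else {
    tibble::tibble(id = integer(), n_cells = integer())
  }
  comp$area_km2 <- comp$n_cells * cell_km2
  mask <- matrix(as.numeric(keep), nrow(lab), ncol(lab))
  mask[is.na(r$values)] <- NA_real_
  structure(list(
    mask = lii_raster(mask, g),
    components = comp,
    total_area_km2 = sum(comp$area_km2),
    threshold = threshold
  ), class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf(
    "<expansion_result> LII > %g: %d component(s), total %.3f km2\n",
    x$threshold, nrow(x$components), x$total_area_km2))
  invisible(x)
}

#' @export
tidy.expansion_result <- function(x, ...) x$components

#' @export
glance.expansion_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_components = nrow(x$components),
                 total_area_km2 = x$total_area_km2)
}

# 8-connected component labels of a logical matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          nb <- (cc - 1L) * nr + rr
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# logical dilation by the 3x3 (8-neighbor) structuring element
dilate8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    c_dst <- max(1, 1 - dc):min(nc, nc - dc)
    out[r_dst, c_dst] <- out[r_dst, c_dst] | mask[r_dst + dr, c_dst + dc]
  }
  out
}

#' Pairwise least-cost corridors between priority areas
#'
#' Rasterizes the priority polygons to the index grid, computes one
#' accumulated-cost surface per priority area over the resistance surface,
#' forms the corridor-value surface for every requested pair, and selects the
#' corridor network at the given land fraction.
#'
#' @param lii An `lii_surface` or [lii_raster()].
#' @param priority [lii_features()] polygon collection of priority areas
#'   (`attrs$gap_status` used by `gap_status` filter), or a binary priority
#'   [lii_raster()] plus `NULL` pairs is not supported (pairs need per-area
#'   identity).
#' @param fraction Selection fraction of non-priority land (default 0.30).
#' @param pairs Optional 2-column matrix of priority-area indices to link;
#'   default all pairs.
#' @param gap_status GAP status codes that qualify an area as protected
#'   priority (default `c(1, 2)`).
#' @param floor Resistance floor, see [resistance_from_lii()].
#' @return An object of class `corridor_result`: list with `selected`
#'   (binary network mask), `combined` (min corridor-value surface),
#'   `per_pair` (list of corridor rasters), `pair_table` (tibble of pair ids
#'   and least-cost totals), `priority_mask`, and `fraction`.
#' @export
build_corridors <- function(lii, priority, fraction = 0.30, pairs = NULL,
                            gap_status = c(1, 2), floor = 1e-6) {
  r <- if (inherits(lii, "lii_surface")) lii$values else lii
  g <- r$grid
  stopifnot(inherits(priority, "lii_features"))
  keep <- rep(TRUE, length(priority$geoms))
  if ("gap_status" %in% names(priority$attrs)) {
    keep <- priority$attrs$gap_status %in% gap_status
  }
  ids <- which(keep)
  if (length(ids) < 2) stop("need >= 2 priority areas to build corridors")
  area_masks <- lapply(ids, function(i) {
    rasterize_features(lii_features(priority$geoms[i], priority$types[i]), g)
  })
  pri_vals <- Reduce(function(a, b) pmax(a, b$values), area_masks,
                     matrix(0, g$n_rows, g$n_cols))
  priority_mask <- lii_raster(pri_vals, g)
  resistance <- resistance_from_lii(r, floor = floor)
  costs <- lapply(area_masks, function(msk) cost_distance(resistance, msk))
  if (is.null(pairs)) pairs <- t(utils::combn(length(ids), 2))
  per_pair <- list(); pair_rows <- list()
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    cs <- corridor_surface(costs[[a]], costs[[b]])
    nm <- sprintf("%d-%d", ids[a], ids[b])
    per_pair[[nm]] <- cs
    tot <- costs[[a]]$values + costs[[b]]$values
    pair_rows[[nm]] <- tibble::tibble(
      source = ids[a], target = ids[b],
      least_cost = min(tot[is.finite(tot)])
    )
  }
  selected <- select_corridors(per_pair, priority_mask, fraction)
  structure(list(
    selected = selected,
    combined = attr(selected, "combined"),
    per_pair = per_pair,
    pair_table = dplyr::bind_rows(pair_rows),
    priority_mask = priority_mask,
    fraction = fraction
  ), class = "corridor_result")
}

#' @export
print.corridor_result <- function(x, ...) {
  cat(sprintf(
    "<corridor_result> %d pair(s), %d selected cell(s) at fraction %.2f\n",
    nrow(x$pair_table), sum(x$selected$values == 1, na.rm = TRUE), x$fraction))
  invisible(x)
}

#' @export
tidy.corridor_result <- function(x, ...) x$pair_table

#' @export
glance.corridor_result <- function(x, ...) {
  sel <- sum(x$selected$values == 1, na.rm = TRUE)
  out <- sum((is.na(x$priority_mask$values) | x$priority_mask$values != 1) &
               !is.na(x$selected$values))
  tibble::tibble(n_pairs = nrow(x$pair_table), fraction = x$fraction,
                 n_selected = sel, selected_fraction = sel / out)
}
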