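#' Specification of a synthetic landscape
#'
#' Desk-scale stand-in for the real data sources the integrity model
#' consumes: random road networks and infrastructure, development and
#' managed-landcover patches, a per-species habitat stack on a 240-m grid, a
#' spatially autocorrelated vegetation-departure field on a 30-m grid, and
#' non-overlapping priority areas plus a three-class land-ownership partition.
#' Everything is reproducible from the single `seed`: each generator derives
#' its own independent sub-stream, so adding a generator never perturbs the
#' output of the others.
#'
#' @param seed Integer master seed.
#' @param width,height Extent in meters (default 9000 x 9000: 100 x 100 cells
#'   at 90 m, small enough for brute-force test oracles).
#' @param pixel_size Model pixel size in meters (default 90).
#' @param n_roads Named counts for the three road classes
#'   (`primitive`, `local`, `highway`).
#' @param n_settlements Number of settlement centers seeding the development
#'   and urban layers.
#' @param n_towers,n_powerlines,n_mines Infrastructure feature counts.
#' @param agriculture_fraction Approximate fraction of the extent covered by
#'   cultivated-agriculture fields, in `[0, 1]`.
#' @param n_landcover_patches Patches per managed-landcover layer (pasture,
#'   grazing, introduced vegetation, low agriculture/invasives).
#' @param n_species Number of species habitat models (default 20).
#' @param n_priority_areas Number of protected priority areas (default 5).
#' @param vdep_smoothness Correlation length (m) of the departure field.
#' @param habitat_smoothness Correlation length (m) of the per-species
#'   suitability fields; longer lengths give broad, regional richness
#'   gradients rather than fine-grained mosaics.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(seed,
                           width = 9000, height = 9000, pixel_size = 90,
                           n_roads = c(primitive = 2, local = 1, highway = 1),
                           n_settlements = 1,
                           n_towers = 1, n_powerlines = 1, n_mines = 1,
                           agriculture_fraction = 0.08,
                           n_landcover_patches = 1,
                           n_species = 20,
                           n_priority_areas = 5,
                           vdep_smoothness = 3000,
                           habitat_smoothness = 3000) {
  stopifnot(width > 0, height > 0, pixel_size > 0,
            agriculture_fraction >= 0, agriculture_fraction <= 1,
            n_species >= 0, n_priority_areas >= 0)
  if (any(c(n_roads, n_settlements, n_towers, n_powerlines, n_mines,
            n_landcover_patches) < 0)) {
    stop("feature counts must be >= 0")
  }
  if (is.null(names(n_roads))) {
    names(n_roads) <- c("primitive", "local", "highway")[seq_along(n_roads)]
  }
  stopifnot(all(c("primitive", "local", "highway") %in% names(n_roads)))
  structure(list(
    seed = as.integer(seed), width = width, height = height,
    pixel_size = pixel_size, n_roads = n_roads,
    n_settlements = n_settlements, n_towers = n_towers,
    n_powerlines = n_powerlines, n_mines = n_mines,
    agriculture_fraction = agriculture_fraction,
    n_landcover_patches = n_landcover_patches,
    n_species = n_species, n_priority_areas = n_priority_areas,
    vdep_smoothness = vdep_smoothness,
    habitat_smoothness = habitat_smoothness
  ), class = "landscape_spec")
}

#' Model grid of a landscape spec
#' @param spec A [landscape_spec()].
#' @param pixel_size Pixel size (m); defaults to the spec's model pixel.
#' @return A [grid_spec()] anchored at (0, height).
#' @export
landscape_grid <- function(spec, pixel_size = spec$pixel_size) {
  grid_spec(0, spec$height, pixel_size,
            ceiling(spec$height / pixel_size),
            ceiling(spec$width / pixel_size))
}

# independent sub-stream seed per generator; keeps results < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629 + 1
}

# ---- feature generation ---------------------------------------------------

random_polyline <- function(width, height, n_waypoints = 3) {
  # crossing line: random points on two different edges plus jittered interior
  edge_point <- function(e) switch(e,
    c(stats::runif(1, 0, width), height), c(stats::runif(1, 0, width), 0),
    c(0, stats::runif(1, 0, height)), c(width, stats::runif(1, 0, height)))
  e <- sample(4, 2)
  p0 <- edge_point(e[1]); p1 <- edge_point(e[2])
  tt <- seq(0, 1, length.out = n_waypoints + 2)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
  mid <- seq_len(n_waypoints) + 1
  pts[mid, ] <- pts[mid, ] + matrix(stats::rnorm(2 * n_waypoints,
                                                 sd = min(width, height) / 25),
                                    n_waypoints, 2)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), width)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), height)
  pts
}

random_blob <- function(cx, cy, radius, n_vertices = 10) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  rr <- radius * stats::runif(n_vertices, 0.6, 1.3)
  ring <- cbind(cx + rr * cos(ang), cy + rr * sin(ang))
  list(rbind(ring, ring[1, , drop = FALSE]))
}

line_collection <- function(n, width, height) {
  lii_features(replicate(n, random_polyline(width, height), simplify = FALSE),
               rep("line", n))
}

point_collection <- function(n, width, height) {
  pts <- lapply(seq_len(n), function(i) {
    c(stats::runif(1, 0, width), stats::runif(1, 0, height))
  })
  lii_features(pts, rep("point", n))
}

blob_collection <- function(n, width, height, r_lo, r_hi, centers = NULL) {
  geoms <- lapply(seq_len(n), function(i) {
    cc <- if (is.null(centers)) c(stats::runif(1, 0, width),
                                  stats::runif(1, 0, height))
          else centers[[(i - 1) %% length(centers) + 1]]
    random_blob(cc[1], cc[2], stats::runif(1, r_lo, r_hi))
  })
  lii_features(geoms, rep("polygon", n))
}

#' Generate synthetic human-land-use features for all 16 configured layers
#'
#' @param spec A [landscape_spec()].
#' @return Named list of [lii_features()] keyed by the 16 default layer
#'   names; layers whose count is zero get an empty collection.
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  w <- spec$width; h <- spec$height
  withr::with_seed(derive_seed(spec$seed, 1), {
    settlements <- lapply(seq_len(max(spec$n_settlements, 1)), function(i) {
      c(stats::runif(1, 0.1 * w, 0.9 * w), stats::runif(1, 0.1 * h, 0.9 * h))
    })
    ns <- spec$n_settlements
    # cultivated fields until the requested fraction of the extent is covered
    ag <- list(); covered <- 0
    while (covered < spec$agriculture_fraction * w * h) {
      side <- stats::runif(1, 0.05, 0.15) * min(w, h)
      x0 <- stats::runif(1, 0, w - side); y0 <- stats::runif(1, 0, h - side)
      ag[[length(ag) + 1]] <- list(rbind(
        c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side), c(x0, y0)))
      covered <- covered + side^2
    }
    npatch <- spec$n_landcover_patches
    list(
      primitive_roads = line_collection(spec$n_roads[["primitive"]], w, h),
      local_roads = line_collection(spec$n_roads[["local"]], w, h),
      major_highways = line_collection(spec$n_roads[["highway"]], w, h),
      low_density_development =
        blob_collection(ns, w, h, 0.04 * w, 0.08 * w, settlements),
      medium_density_development =
        blob_collection(if (ns > 0) max(ns - 1, 0) else 0,
                        w, h, 0.02 * w, 0.05 * w, settlements),
      high_density_development =
        blob_collection(if (ns > 0) 1 else 0, w, h, 0.01 * w, 0.03 * w,
                        settlements),
      communication_towers = point_collection(spec$n_towers, w, h),
      powerlines = line_collection(spec$n_powerlines, w, h),
      mines_and_well_pads = point_collection(spec$n_mines, w, h),
      urban_polygons =
        blob_collection(if (ns > 0) 1 else 0, w, h, 0.02 * w, 0.04 * w,
                        settlements),
      high_impervious_surfaces =
        blob_collection(if (ns > 0) 1 else 0, w, h, 0.01 * w, 0.02 * w,
                        settlements),
      low_agriculture_and_invasives =
        blob_collection(npatch, w, h, 0.03 * w, 0.08 * w),
      pasture = blob_collection(npatch, w, h, 0.03 * w, 0.08 * w),
      grazing_allotments = blob_collection(npatch, w, h, 0.08 * w, 0.15 * w),
      introduced_vegetation = blob_collection(npatch, w, h, 0.02 * w, 0.06 * w),
      cultivated_agriculture = lii_features(ag, rep("polygon", length(ag)))
    )
  })
}

# separable box smoothing with reflection padding; halfwidth in cells
smooth_box <- function(m, halfwidth) {
  k <- as.integer(halfwidth)
  if (k < 1) return(m)
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(min(k, n))]), x, rev(x[n + 1 - seq_len(min(k, n))]))
    f <- stats::filter(xp, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    as.numeric(f[(min(k, n) + 1):(min(k, n) + n)])
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

# smoothed standard-normal field rescaled to [0, 1]
smooth_field <- function(n_rows, n_cols, halfwidth) {
  f <- smooth_box(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                  halfwidth)
  rng <- range(f)
  if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else f * 0 + 0.5
}

#' Generate a synthetic habitat-suitability stack
#'
#' One categorical suitability model per species on the 240-m grid: a smooth
#' random field cut at its quartiles into codes 0-3 (0 = unsuitable). The
#' generator retains the true per-cell richness (count of species with a
#' nonzero code) as attribute `truth_counts` for oracle tests.
#'
#' @param spec A [landscape_spec()].
#' @return List of [habitat_model()]s with attribute `truth_counts`
#'   (an [lii_raster()] of the generator-known richness).
#' @export
generate_habitat_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"), spec$n_species >= 1)
  g <- landscape_grid(spec, 240)
  withr::with_seed(derive_seed(spec$seed, 2), {
    truth <- matrix(0, g$n_rows, g$n_cols)
    models <- lapply(seq_len(spec$n_species), function(i) {
      f <- smooth_field(g$n_rows, g$n_cols,
                        halfwidth = floor(spec$habitat_smoothness / 240))
      codes <- matrix(findInterval(f, stats::quantile(f, c(0.2, 0.5, 0.75))),
                      g$n_rows, g$n_cols)
      truth <<- truth + (codes > 0)
      habitat_model(sprintf("species_%02d", i), lii_raster(codes, g))
    })
    attr(models, "truth_counts") <- lii_raster(truth, g)
    models
  })
}

#' Generate a synthetic vegetation-departure field
#'
#' Spatially autocorrelated noise (separable box smoothing with half-width
#' `vdep_smoothness`) rescaled to the full `[0, 100]` departure range on a
#' 30-m grid. A smoothness below one cell yields independent per-cell noise.
#'
#' @param spec A [landscape_spec()].
#' @return An [lii_raster()] with values in `[0, 100]`.
#' @export
generate_vdep <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  g <- landscape_grid(spec, 30)
  withr::with_seed(derive_seed(spec$seed, 3), {
    f <- smooth_field(g$n_rows, g$n_cols,
                      halfwidth = floor(spec$vdep_smoothness / 30))
    lii_raster(f^2.5 * 100, g)
  })
}

#' Generate priority areas and a land-ownership partition
#'
#' Priority areas are pairwise-disjoint polygons (circle-ish blobs placed by
#' rejection sampling) tagged with GAP status 1 or 2. Ownership is a
#' three-class partition of the extent (federal / private / state), realized
#' as the nearest-seed (Voronoi) classification of the model grid with every
#' class guaranteed present.
#'
#' @param spec A [landscape_spec()].
#' @return List with `priority` ([lii_features()] with `attrs` columns `id`
#'   and `gap_status`), `ownership` ([lii_raster()] of class codes 1-3) and
#'   `ownership_classes` (code labels).
#' @export
generate_priority_areas <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  w <- spec$width; h <- spec$height
  g <- landscape_grid(spec)
  withr::with_seed(derive_seed(spec$seed, 4), {
    centers <- matrix(numeric(), 0, 2)
    radii <- numeric()
    tries <- 0
    while (nrow(centers) < spec$n_priority_areas && tries < 10000) {
      tries <- tries + 1
      r <- stats::runif(1, 0.05, 0.09) * min(w, h)
      cx <- stats::runif(1, r, w - r); cy <- stats::runif(1, r, h - r)
      # 1.35 x blob max vertex factor keeps jittered rings disjoint
      if (!nrow(centers) ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                (radii + r) * 1.35)) {
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, r)
      }
    }
    if (nrow(centers) < spec$n_priority_areas) {
      stop("could not place disjoint priority areas; reduce count or size")
    }
    geoms <- lapply(seq_len(nrow(centers)), function(i) {
      random_blob(centers[i, 1], centers[i, 2], radii[i], n_vertices = 12)
    })
    priority <- lii_features(
      geoms, rep("polygon", length(geoms)),
      tibble::tibble(id = sprintf("pa_%d", seq_along(geoms)),
                     gap_status = sample(c(1, 2), length(geoms), replace = TRUE))
    )
    classes <- c("federal", "private", "state")
    n_seeds <- 6
    seed_xy <- cbind(stats::runif(n_seeds, 0, w), stats::runif(n_seeds, 0, h))
    seed_cls <- c(1:3, sample(3, n_seeds - 3, replace = TRUE))
    cen <- cell_centers_colmajor(g)
    d2 <- sapply(seq_len(n_seeds), function(i) {
      (cen$x - seed_xy[i, 1])^2 + (cen$y - seed_xy[i, 2])^2
    })
    own <- seed_cls[max.col(-d2, ties.method = "first")]
    list(
      priority = priority,
      ownership = lii_raster(matrix(own, g$n_rows, g$n_cols), g),
      ownership_classes = classes
    )
  })
}

#' Generate a complete synthetic landscape
#'
#' @param spec A [landscape_spec()].
#' @return List with `features`, `habitat` (with richness ground truth),
#'   `vdep`, `priority`, `ownership`, `ownership_classes`, `grid` (the model
#'   grid) and `spec`.
#' @export
generate_landscape <- function(spec) {
  pa <- generate_priority_areas(spec)
  list(
    features = generate_features(spec),
    habitat = if (spec$n_species >= 1) generate_habitat_stack(spec) else list(),
    vdep = generate_vdep(spec),
    priority = pa$priority,
    ownership = pa$ownership,
    ownership_classes = pa$ownership_classes,
    grid = landscape_grid(spec),
    spec = spec
  )
}
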