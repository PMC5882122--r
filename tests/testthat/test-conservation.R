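test_that("resistance is the floored complement of integrity", {
  r <- make_raster(matrix(c(1, 0, 0.75, 0.5), 2, 2))
  res <- raster_values(resistance_from_lii(r, floor = 1e-6))
  expect_equal(res[1, 1], 1e-6)
  expect_equal(res[2, 1], 1)
  expect_equal(res[1, 2], 0.25, tolerance = 1e-15)
  expect_true(all(res > 0))
  lit <- raster_values(resistance_from_lii(r, floor = 1e-6, literal = TRUE))
  expect_equal(lit[2, 1], 1e-6)
  expect_equal(lit[1, 1], 1)
})

test_that("cost distance equals the chamfer metric under uniform resistance", {
  g <- make_grid(5, 5)
  res <- lii_raster(matrix(1, 5, 5), g)
  src <- lii_raster(matrix(c(1, rep(0, 24)), 5, 5), g)
  d <- raster_values(cost_distance(res, src))
  for (r in 1:5) for (cc in 1:5) {
    dr <- r - 1; dc <- cc - 1
    expect_equal(d[r, cc], abs(dr - dc) + sqrt(2) * min(dr, dc),
                 tolerance = 1e-12)
  }
  expect_equal(d[1, 1], 0)
})

test_that("cost distance matches the array Dijkstra oracle and scales linearly", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(8:15, 1)
    resm <- matrix(runif(n * n, 0.05, 2), n, n)
    srcm <- matrix(0, n, n)
    srcm[sample(n * n, 2)] <- 1
    g <- make_grid(n, n)
    got <- raster_values(cost_distance(lii_raster(resm, g), lii_raster(srcm, g)))
    want <- oracle_cost_distance(resm, srcm == 1)
    expect_equal(got, want, tolerance = 1e-12)
    # doubling resistance doubles every accumulated cost
    got2 <- raster_values(cost_distance(lii_raster(2 * resm, g),
                                        lii_raster(srcm, g)))
    expect_equal(got2, 2 * got, tolerance = 1e-12)
  }
  g <- make_grid(3, 3)
  expect_error(cost_distance(lii_raster(matrix(1, 3, 3), g),
                             lii_raster(matrix(0, 3, 3), g)), "source")
  expect_error(cost_distance(lii_raster(matrix(c(-1, rep(1, 8)), 3, 3), g),
                             lii_raster(matrix(1, 3, 3), g)), "resistance")
})

test_that("corridor surfaces are zero along the least-cost path", {
  g <- make_grid(5, 9)
  res <- lii_raster(matrix(1, 5, 9), g)
  a <- matrix(0, 5, 9); a[3, 1] <- 1
  b <- matrix(0, 5, 9); b[3, 9] <- 1
  ca <- cost_distance(res, lii_raster(a, g))
  cb <- cost_distance(res, lii_raster(b, g))
  corr <- raster_values(corridor_surface(ca, cb))
  expect_equal(min(corr), 0)
  # under uniform resistance the straight row between the endpoints is optimal
  expect_true(all(abs(corr[3, ]) < 1e-12))
  expect_true(all(corr >= -1e-12))
  # scaling resistance scales corridor values, leaving the zero set unchanged
  ca2 <- cost_distance(lii_raster(3 * raster_values(res), g), lii_raster(a, g))
  cb2 <- cost_distance(lii_raster(3 * raster_values(res), g), lii_raster(b, g))
  corr2 <- raster_values(corridor_surface(ca2, cb2))
  expect_equal(corr2, 3 * corr, tolerance = 1e-10)
})

test_that("corridor selection hits the requested land fraction and nests", {
  set.seed(9)
  n <- 20
  g <- make_grid(n, n)
  res <- lii_raster(matrix(runif(n * n, 0.1, 1), n, n), g)
  a <- matrix(0, n, n); a[2, 2] <- 1
  b <- matrix(0, n, n); b[n - 1, n - 1] <- 1
  corr <- corridor_surface(cost_distance(res, lii_raster(a, g)),
                           cost_distance(res, lii_raster(b, g)))
  pri <- matrix(0, n, n); pri[1:3, 1:3] <- 1; pri[(n - 2):n, (n - 2):n] <- 1
  pri_r <- lii_raster(pri, g)
  n_out <- sum(pri != 1)
  sel <- select_corridors(list(corr), pri_r, 0.30)
  k <- sum(raster_values(sel) == 1, na.rm = TRUE)
  expect_lte(abs(k - 0.30 * n_out), 1)
  # least-cost-path (zero-value) cells outside priority areas always selected
  zero_out <- which(corr$values == 0 & pri != 1)
  expect_true(all(raster_values(sel)[zero_out] == 1))
  # nothing selected inside priority areas
  expect_true(all(raster_values(sel)[pri == 1] == 0))
  # nesting in the fraction
  sel_small <- raster_values(select_corridors(list(corr), pri_r, 0.10))
  sel_large <- raster_values(select_corridors(list(corr), pri_r, 0.45))
  expect_true(all(sel_large[sel_small == 1] == 1))
  expect_true(all(raster_values(select_corridors(list(corr), pri_r, 0.999))[pri != 1] == 1))
  expect_error(select_corridors(list(corr), pri_r, 1.2), "fraction")
})

test_that("expansion keeps only supra-threshold components touching priority areas", {
  g <- make_grid(10, 10)
  v <- matrix(0.4, 10, 10)
  v[2:4, 2:4] <- 0.9        # touches the priority block at (5,5)
  v[8:9, 8:9] <- 0.95       # isolated
  pri <- matrix(0, 10, 10); pri[5, 5] <- 1
  er <- expansion_areas(lii_raster(v, g), lii_raster(pri, g), 0.70)
  expect_equal(nrow(er$components), 1)
  m <- raster_values(er$mask)
  expect_true(all(m[2:4, 2:4] == 1))
  expect_true(all(m[8:9, 8:9] == 0))
  expect_equal(er$total_area_km2, 9 * (90 / 1000)^2, tolerance = 1e-12)
  # uniformly below threshold: empty result
  low <- expansion_areas(lii_raster(matrix(0.5, 10, 10), g),
                         lii_raster(pri, g), 0.70)
  expect_equal(nrow(low$components), 0)
  expect_equal(low$total_area_km2, 0)
})

test_that("expansion agrees with a flood-fill oracle and shrinks with threshold", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(runif(900), 30, 30)
    pri <- matrix(0, 30, 30)
    pri[14:16, 14:16] <- 1
    g <- make_grid(30, 30)
    er <- expansion_areas(lii_raster(v, g), lii_raster(pri, g), 0.60)
    high <- v > 0.60 & pri != 1
    # seeds: supra-threshold cells 8-adjacent to a priority cell
    near <- matrix(FALSE, 30, 30)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(row(pri) + dr, 1), 30)
      cs <- pmin(pmax(col(pri) + dc, 1), 30)
      near <- near | pri[cbind(as.vector(rs), as.vector(cs))] == 1
    }
    want <- oracle_flood_fill(high, near & high)
    expect_identical(raster_values(er$mask) == 1, want)
    # monotone: total area non-increasing in the threshold
    areas <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
      expansion_areas(lii_raster(v, g), lii_raster(pri, g), th)$total_area_km2
    }, numeric(1))
    expect_true(all(diff(areas) <= 1e-12))
  }
})

test_that("pairwise corridor building links priority polygons end to end", {
  sp <- landscape_spec(seed = 5, n_priority_areas = 3)
  ls <- generate_landscape(sp)
  surf <- structure(list(
    values = lii_raster(matrix(runif(ls$grid$n_rows * ls$grid$n_cols, 0.2, 0.9),
                               ls$grid$n_rows, ls$grid$n_cols), ls$grid),
    window_radius = 1000, weights = rep(1 / 3, 3)), class = "lii_surface")
  cr <- build_corridors(surf, ls$priority, fraction = 0.25)
  expect_equal(nrow(cr$pair_table), choose(3, 2))
  expect_true(all(cr$pair_table$least_cost > 0))
  gl <- glance(cr)
  expect_lt(abs(gl$selected_fraction - 0.25), 1e-3)
  # explicit pair list restricts the network
  cr2 <- build_corridors(surf, ls$priority, fraction = 0.25,
                         pairs = matrix(c(1, 2), 1))
  expect_equal(nrow(cr2$pair_table), 1)
})
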