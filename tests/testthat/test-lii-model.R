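test_that("focal mean matches the nested-loop window oracle", {
  # constants are fixed points
  cst <- make_raster(matrix(3.7, 6, 6))
  expect_true(all(abs(raster_values(focal_mean(cst, 1000)) - 3.7) < 1e-12))
  # radius of one pixel: the 4-neighborhood plus self
  set.seed(12)
  m <- matrix(runif(49), 7, 7)
  got <- raster_values(focal_mean(make_raster(m), 90))
  expect_equal(got[4, 4], mean(c(m[4, 4], m[3, 4], m[5, 4], m[4, 3], m[4, 5])),
               tolerance = 1e-12)
  expect_equal(got, oracle_focal(m, 90, 90), tolerance = 1e-12)
  # full 1-km window on a 15x15, with nodata holes
  m2 <- matrix(runif(225), 15, 15)
  m2[sample(225, 12)] <- NA
  got2 <- raster_values(focal_mean(make_raster(m2), 1000))
  expect_equal(got2, oracle_focal(m2, 1000, 90), tolerance = 1e-10)
  # interior translation-equivariance: shifting the input shifts the output
  shifted <- m2[, c(2:15, 1)]
  gs <- raster_values(focal_mean(make_raster(shifted), 270))
  expect_equal(gs[5:11, 5:10], got_shift <- raster_values(
    focal_mean(make_raster(m2), 270))[5:11, 6:11], tolerance = 1e-12)
  expect_error(focal_mean(make_raster(m), 45), "pixel")
})

test_that("index surface is the smoothed equal-weight indicator mean in [0, 1]", {
  g <- make_grid(9, 9)
  mk <- function(v) lii_raster(matrix(v, 9, 9), g)
  s <- compute_lii(mk(0.6), mk(0.3), mk(0.9))
  expect_true(all(abs(raster_values(s$values) - 0.6) < 1e-12))
  s1 <- compute_lii(mk(1), mk(1), mk(1))
  expect_true(all(raster_values(s1$values) == 1))
  expect_error(compute_lii(mk(1), mk(1), mk(1), weights = c(1, 1, 1)), "sum")
  # monotone in each indicator
  set.seed(31)
  a <- mk(runif(81)); b <- mk(runif(81)); cc <- mk(runif(81))
  base <- raster_values(compute_lii(a, b, cc)$values)
  a2 <- a; a2$values[5, 5] <- min(1, a$values[5, 5] + 0.3)
  bumped <- raster_values(compute_lii(a2, b, cc)$values)
  expect_true(all(bumped - base >= -1e-15))
})

test_that("layer-averaging and focal-averaging commute on full windows", {
  set.seed(14)
  g <- make_grid(20, 20)
  ind <- lapply(1:3, function(i) lii_raster(matrix(runif(400), 20, 20), g))
  mixed_first <- compute_lii(ind[[1]], ind[[2]], ind[[3]], radius = 500)
  focal_first <- (raster_values(focal_mean(ind[[1]], 500)) +
                  raster_values(focal_mean(ind[[2]], 500)) +
                  raster_values(focal_mean(ind[[3]], 500))) / 3
  expect_equal(raster_values(mixed_first$values), focal_first,
               tolerance = 1e-12)
})

test_that("random sampling is reproducible, valid, and stratifiable", {
  g <- make_grid(30, 30)
  mask_vals <- matrix(1, 30, 30)
  mask_vals[1:5, 1:5] <- NA
  mask <- lii_raster(mask_vals, g)
  p1 <- sample_points(mask, 100, seed = 42)
  p2 <- sample_points(mask, 100, seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 100)
  expect_equal(nrow(dplyr::distinct(p1, row, col)), 100)
  expect_true(all(!is.na(mask$values[cbind(p1$row, p1$col)])))
  p3 <- sample_points(mask, 100, seed = 43)
  expect_false(identical(p1$row, p3$row))
  # stratified: 50 per class
  strata <- lii_raster(matrix(rep(c(1, 2), each = 450), 30, 30), g)
  ps <- sample_points(mask, 50, strata = strata, seed = 7)
  expect_equal(nrow(ps), 100)
  expect_equal(unname(table(ps$stratum)), c(50L, 50L), ignore_attr = TRUE)
  expect_error(sample_points(mask, 1e5, seed = 1), "insufficient")
  # polygon strata
  half <- lii_features(
    list(list(rbind(c(0, 0), c(2700, 0), c(2700, 2700), c(0, 2700), c(0, 0)))),
    "polygon", tibble::tibble(owner = "south"))
  pp <- sample_points(mask, 10, strata = half, seed = 3)
  expect_true(all(pp$stratum == "south"))
  expect_true(all(pp$y < 2700))
})

test_that("Welch t statistic matches the hand-computed equal-variance case", {
  w <- welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(w$statistic, -1, tolerance = 1e-12)
  expect_equal(w$df, 8, tolerance = 1e-12)
  # identical samples differ only by noise-free zero
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0, tolerance = 1e-15)
  # antisymmetry
  sw <- welch_t_test(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(sw$statistic, 1, tolerance = 1e-12)
  expect_equal(sw$p_value, w$p_value, tolerance = 1e-15)
  expect_error(welch_t_test(c(1, 1), c(1, 2)), "variance")
  td <- tidy(w)
  expect_equal(td$estimate1, 3)
  expect_equal(td$parameter, 8)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  an <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5)))
  expect_equal(an$statistic, 3, tolerance = 1e-12)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  # all-identical groups: F = 0
  z <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(z$statistic, 0)
  # 3 groups of 50 report df (2, 147)
  set.seed(2)
  big <- one_way_anova(lapply(1:3, function(i) rnorm(50, i)))
  expect_equal(c(big$df_between, big$df_within), c(2, 147))
  expect_error(one_way_anova(list(c(1, 2))), "groups")
  g <- glance(big)
  expect_equal(g$df_within, 147)
})

test_that("post-hoc letters reflect Tukey HSD group separation", {
  # identical groups share a letter
  same <- pairwise_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)), alpha = 0.01)
  expect_equal(same$letter[1], same$letter[2])
  # extreme separation: different letters
  far <- pairwise_posthoc(list(lo = rnorm(10, 0, 0.01),
                               hi = rnorm(10, 100, 0.01)), alpha = 0.01)
  expect_false(far$letter[far$group == "lo"] == far$letter[far$group == "hi"])
  # constructed a/ab/b pattern: only the outer pair differs. Unit-variance
  # deterministic base with shifts 0 / 1.1 / 2.2: adjacent studentized ranges
  # sit below the alpha = 0.01 critical value, the outer one above it
  base <- as.numeric(scale(1:10))
  g1 <- base; g2 <- base + 1.1; g3 <- base + 2.2
  ph <- pairwise_posthoc(list(g1 = g1, g2 = g2, g3 = g3), alpha = 0.01)
  pm <- attr(ph, "p_matrix")
  # verify the constructed case really has exactly one significant pair
  expect_true(pm["g1", "g3"] < 0.01)
  expect_true(pm["g1", "g2"] >= 0.01 && pm["g2", "g3"] >= 0.01)
  l <- setNames(ph$letter, ph$group)
  expect_false(any(strsplit(l[["g1"]], "")[[1]] %in% strsplit(l[["g3"]], "")[[1]]))
  expect_true(any(strsplit(l[["g2"]], "")[[1]] %in% strsplit(l[["g1"]], "")[[1]]))
  expect_true(any(strsplit(l[["g2"]], "")[[1]] %in% strsplit(l[["g3"]], "")[[1]]))
})

test_that("Pearson correlation matches hand computation and bounds", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1, tolerance = 1e-12)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
               tolerance = 1e-12)
  expect_error(pearson_correlation(1:3, 1:4), "length")
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})
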