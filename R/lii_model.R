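#' Circular moving-window mean
#'
#' Each output cell is the mean of all valid input cells whose centers lie
#' within `radius` meters of the focal cell center (center distance,
#' inclusive). Nodata cells are excluded from the mean; a cell with at least
#' one valid neighbor (itself included) gets a value, otherwise nodata. A
#' square window (Chebyshev distance) is available for comparison with
#' square-kernel focal statistics.
#'
#' @param r Input [lii_raster()].
#' @param radius Window radius in meters; must be >= the pixel size.
#' @param shape `"circle"` (default) or `"square"`.
#' @return Smoothed [lii_raster()].
#' @export
focal_mean <- function(r, radius, shape = c("circle", "square")) {
  stopifnot(inherits(r, "lii_raster"))
  shape <- match.arg(shape)
  px <- r$grid$pixel_size
  if (radius < px) {
    stop(sprintf("radius (%g m) must be at least the pixel size (%g m)",
                 radius, px))
  }
  k <- floor(radius / px + 1e-9)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  if (shape == "circle") {
    keep <- (offs$dr^2 + offs$dc^2) * px^2 <= radius^2 * (1 + 1e-12)
    offs <- offs[keep, ]
  }
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  vz <- ifelse(valid, v, 0)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    # input cell (r + dr, c + dc) contributes to focal cell (r, c)
    r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    r_dst <- r0:r1
    c_dst <- c0:c1
    r_src <- r_dst + dr
    c_src <- c_dst + dc
    acc[r_dst, c_dst] <- acc[r_dst, c_dst] + vz[r_src, c_src]
    cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + valid[r_src, c_src]
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  with_values(r, matrix(out, nr, nc))
}

#' Compute the Landscape Integrity Index surface
#'
#' Cellwise weighted mean of the three indicator surfaces (human influence,
#' normalized species richness, normalized inverse vegetation departure),
#' followed by a circular moving-window mean of the given radius. All three
#' indicators must already live on the shared model grid (see [resample()]);
#' the `richness_surface` / `vdep_surface` wrappers are unwrapped to their
#' normalized rasters automatically. With equal window footprints and no
#' nodata, averaging indicators before or after the focal pass is exactly
#' equivalent (both are linear); the indicator average is taken first so a
#' single focal pass suffices.
#'
#' @param hii Composite human-influence [lii_raster()] in `[0, 1]`.
#' @param richness Normalized richness [lii_raster()] (or a
#'   [stack_richness()] result).
#' @param vdep Normalized inverse departure [lii_raster()] (or a
#'   [normalize_inverse_vdep()] result).
#' @param radius Moving-window radius in meters (default 1000).
#' @param weights Indicator weights `(hii, richness, vdep)`; must sum to 1
#'   (default equal).
#' @param shape Window shape, see [focal_mean()].
#' @return An object of class `lii_surface`: list with `values` (the LII
#'   [lii_raster()]), `window_radius` and `weights`.
#' @export
compute_lii <- function(hii, richness, vdep, radius = 1000,
                        weights = c(1, 1, 1) / 3, shape = "circle") {
  if (inherits(richness, "richness_surface")) richness <- richness$normalized
  if (inherits(vdep, "vdep_surface")) vdep <- vdep$normalized_inverse
  if (length(weights) != 3 || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a length-3 vector summing to 1")
  }
  check_shared_grid(list(hii, richness, vdep))
  mixed <- weights[1] * hii$values + weights[2] * richness$values +
    weights[3] * vdep$values
  sm <- focal_mean(with_values(hii, mixed), radius, shape)
  structure(list(values = sm, window_radius = radius, weights = weights),
            class = "lii_surface")
}

#' @export
print.lii_surface <- function(x, ...) {
  v <- x$values$values[!is.na(x$values$values)]
  cat(sprintf(
    "<lii_surface> %s, window %g m, weights (%.3g, %.3g, %.3g), LII [%.3f, %.3f]\n",
    format(x$values$grid), x$window_radius, x$weights[1], x$weights[2],
    x$weights[3], min(v), max(v)))
  invisible(x)
}

#' @export
autoplot.lii_surface <- function(object, ...) {
  autoplot.lii_raster(object$values, name = "LII", ...)
}

# ---- random sampling ------------------------------------------------------

#' Draw random sample points on valid cells
#'
#' Uniform sampling of cell centers without replacement within the valid part
#' of the mask; with `strata` given, `n` points are drawn within each stratum.
#' Sampling is reproducible from `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param valid_mask [lii_raster()]; cells that are non-nodata and nonzero are
#'   eligible.
#' @param n Number of points (per stratum when `strata` is given).
#' @param strata Optional stratification: an [lii_raster()] of stratum codes,
#'   or an [lii_features()] polygon collection whose `attrs` column
#'   `strata_field` labels each polygon. Cells outside every stratum are
#'   excluded.
#' @param seed Integer seed.
#' @param strata_field Attribute column naming strata for polygon input.
#' @return A tibble with columns `x`, `y`, `row`, `col`, `stratum`.
#' @export
sample_points <- function(valid_mask, n, strata = NULL, seed = 1,
                          strata_field = NULL) {
  stopifnot(inherits(valid_mask, "lii_raster"), n >= 1)
  g <- valid_mask$grid
  eligible <- !is.na(valid_mask$values) & valid_mask$values != 0
  labels <- stratum_labels(strata, g, strata_field)
  if (!is.null(labels)) eligible <- eligible & !is.na(labels)
  strata_levels <- if (is.null(labels)) NA_character_ else
    sort(unique(labels[eligible]))
  picks <- withr::with_seed(seed, {
    unlist(lapply(strata_levels, function(s) {
      cells <- if (is.null(labels)) which(eligible) else
        which(eligible & labels == s)
      if (length(cells) < n) {
        stop(sprintf("insufficient valid cells (%d) to draw %d point(s)%s",
                     length(cells), n,
                     if (is.na(s)) "" else sprintf(" in stratum '%s'", s)))
      }
      sample(cells, n)
    }))
  })
  rows <- ((picks - 1) %% g$n_rows) + 1
  cols <- ((picks - 1) %/% g$n_rows) + 1
  tibble::tibble(
    x = g$x_origin + (cols - 0.5) * g$pixel_size,
    y = g$y_origin - (rows - 0.5) * g$pixel_size,
    row = rows, col = cols,
    stratum = if (is.null(labels)) NA_character_ else
      rep(strata_levels, each = n)
  )
}

# stratum label per cell (column-major matrix), or NULL
stratum_labels <- function(strata, grid, strata_field = NULL) {
  if (is.null(strata)) return(NULL)
  if (inherits(strata, "lii_raster")) {
    if (!same_grid(strata$grid, grid)) stop("strata raster grid mismatch")
    return(matrix(as.character(strata$values), grid$n_rows, grid$n_cols))
  }
  if (inherits(strata, "lii_features")) {
    if (is.null(strata_field)) strata_field <- names(strata$attrs)[1]
    if (is.null(strata_field) || !strata_field %in% names(strata$attrs)) {
      stop("strata polygons need a label column (strata_field)")
    }
    lab <- matrix(NA_character_, grid$n_rows, grid$n_cols)
    cen <- cell_centers_colmajor(grid)
    for (i in seq_along(strata$geoms)) {
      if (strata$types[i] != "polygon") stop("strata features must be polygons")
      inside <- rep(FALSE, length(cen$x))
      for (ring in strata$geoms[[i]]) {
        inside <- xor(inside, ring_contains(cen$x, cen$y, ring))
      }
      lab[matrix(inside, grid$n_rows, grid$n_cols)] <-
        as.character(strata$attrs[[strata_field]][i])
    }
    return(lab)
  }
  stop("strata must be an lii_raster or lii_features polygon collection")
}

#' Extract raster values at sample points
#'
#' @param r An [lii_raster()].
#' @param points Tibble from [sample_points()] (needs `row`, `col`).
#' @return `points` with a `value` column appended.
#' @export
extract_values <- function(r, points) {
  stopifnot(inherits(r, "lii_raster"), all(c("row", "col") %in% names(points)))
  dplyr::mutate(points, value = r$values[cbind(points$row, points$col)])
}

# ---- statistics -----------------------------------------------------------

#' Broom-style tidiers
#'
#' `tidy()` returns a one-row-per-term tibble, `glance()` a one-row model
#' summary, for the package's fitted comparison objects.
#'
#' @param x A fitted object (`lii_ttest`, `lii_anova`).
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided Student-t p-value, as used to compare index scores between
#' protected and unprotected samples.
#'
#' @param a,b Numeric samples, each with >= 2 values and nonzero variance.
#' @return An object of class `lii_ttest` with fields `statistic`, `df`,
#'   `p_value`, `estimate` (the two means); supports [tidy()] and [glance()].
#' @examples
#' welch_t_test(1:5, 2:6)
#' @export
welch_t_test <- function(a, b) {
  check_sample(a, "a"); check_sample(b, "b")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = unname(ht$estimate),
    method = "Welch two-sample t-test"
  ), class = "lii_ttest")
}

check_sample <- function(x, name) {
  if (length(x) < 2 || stats::var(x) == 0 || anyNA(x)) {
    stop(sprintf("sample '%s' needs >= 2 complete values with nonzero variance",
                 name))
  }
}

#' @export
print.lii_ttest <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, df = %.3f, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.lii_ttest <- function(x, ...) {
  tibble::tibble(
    estimate1 = x$estimate[1], estimate2 = x$estimate[2],
    statistic = x$statistic, parameter = x$df, p.value = x$p_value,
    method = x$method
  )
}

#' @export
glance.lii_ttest <- function(x, ...) tidy.lii_ttest(x)

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA of a numeric response across k groups:
#' F = MS_between / MS_within with degrees of freedom (k - 1, N - k).
#'
#' @param groups Named (or unnamed) list of >= 2 numeric samples, each with
#'   >= 2 values.
#' @return An object of class `lii_anova` with fields `statistic` (F),
#'   `df_between`, `df_within`, `p_value`, and the underlying `aov` fit;
#'   supports [tidy()] and [glance()].
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  if (stats::var(df$value) == 0) {
    # all observations identical: F is 0 by definition, aov would divide 0/0
    return(structure(list(
      statistic = 0, df_between = length(groups) - 1,
      df_within = nrow(df) - length(groups), p_value = 1,
      fit = NULL, data = df
    ), class = "lii_anova"))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- stats::anova(fit)
  structure(list(
    statistic = tab$`F value`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    p_value = tab$`Pr(>F)`[1],
    fit = fit, data = df
  ), class = "lii_anova")
}

#' @export
print.lii_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.lii_anova <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$data, .data$group),
                   n = dplyr::n(), mean = mean(.data$value),
                   sd = stats::sd(.data$value), .groups = "drop")
}

#' @export
glance.lii_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_between = x$df_between,
                 df_within = x$df_within, p.value = x$p_value)
}

#' Tukey HSD post-hoc comparisons with a compact letter display
#'
#' All pairwise group comparisons under the studentized-range (Tukey HSD)
#' null on the ANOVA fit; groups that are not significantly different at
#' `alpha` share a letter (insert-absorb compact letter display, letters
#' assigned in order of decreasing group mean).
#'
#' @param groups As in [one_way_anova()].
#' @param alpha Familywise significance level (default 0.01).
#' @return A tibble with columns `group`, `n`, `mean`, `letter`; the pairwise
#'   adjusted p-value matrix is attached as attribute `p_matrix`.
#' @export
pairwise_posthoc <- function(groups, alpha = 0.01) {
  an <- one_way_anova(groups)
  k <- nlevels(an$data$group)
  lev <- levels(an$data$group)
  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  if (!is.null(an$fit)) {
    tk <- stats::TukeyHSD(an$fit)$group
    for (cmp in rownames(tk)) {
      pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[cmp, "p adj"]
    }
  }
  means <- vapply(split(an$data$value, an$data$group), mean, numeric(1))
  letters_out <- letter_display(pmat, means, alpha)
  out <- tibble::tibble(
    group = lev,
    n = as.integer(table(an$data$group)[lev]),
    mean = unname(means[lev]),
    letter = unname(letters_out[lev])
  )
  attr(out, "p_matrix") <- pmat
  out
}

# insert-absorb compact letter display
letter_display <- function(pmat, means, alpha) {
  lev <- names(means)[order(-means)]
  cols <- list(lev)  # letter columns, each a set of group names
  for (i in seq_along(lev)) {
    for (j in seq_len(i - 1)) {
      if (pmat[lev[i], lev[j]] < alpha) {
        for (ci in seq_along(cols)) {
          if (all(c(lev[i], lev[j]) %in% cols[[ci]])) {
            cols[[length(cols) + 1]] <- setdiff(cols[[ci]], lev[i])
            cols[[ci]] <- setdiff(cols[[ci]], lev[j])
          }
        }
        # absorb columns that became subsets of another
        keep <- rep(TRUE, length(cols))
        for (ci in seq_along(cols)) {
          for (cj in seq_along(cols)) {
            if (ci != cj && keep[cj] &&
                all(cols[[ci]] %in% cols[[cj]]) &&
                (length(cols[[ci]]) < length(cols[[cj]]) || ci > cj)) {
              keep[ci] <- FALSE
              break
            }
          }
        }
        cols <- cols[keep]
      }
    }
  }
  # order columns by the best-ranked group they contain, then letter them
  first_rank <- vapply(cols, function(s) min(match(s, lev)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (>= 3 values, nonzero variance).
#' @return The sample correlation coefficient r in `[-1, 1]`.
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 paired values")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  stats::cor(x, y, method = "pearson")
}
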