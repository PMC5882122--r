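#' Run the full landscape-integrity pipeline on a synthetic landscape
#'
#' Convenience wrapper chaining every stage: rasterize the human-land-use
#' features and build the composite human-influence surface, stack and
#' normalize species richness (240 m, resampled bilinearly to the model
#' grid), normalize inverse vegetation departure (30 m, resampled
#' bilinearly), compute the moving-window integrity surface, and optionally
#' run the two conservation-planning applications (corridor network and
#' priority-adjacent expansion).
#'
#' @param landscape Output of [generate_landscape()] (or a [landscape_spec()],
#'   which is generated first).
#' @param config Layer configuration (default [default_layer_config()]).
#' @param radius Moving-window radius in meters (default 1000).
#' @param weights Indicator weights, see [compute_lii()].
#' @param fraction Corridor selection fraction (default 0.30).
#' @param threshold Expansion integrity cutoff (default 0.70).
#' @param planning Run the corridor / expansion applications (default TRUE).
#' @return List with `hii`, `richness`, `vdep`, `lii`, and (when `planning`)
#'   `corridors` and `expansion`, plus the input `landscape`.
#' @export
lii_pipeline <- function(landscape, config = default_layer_config(),
                         radius = 1000, weights = c(1, 1, 1) / 3,
                         fraction = 0.30, threshold = 0.70, planning = TRUE) {
  if (inherits(landscape, "landscape_spec")) {
    landscape <- generate_landscape(landscape)
  }
  grid <- landscape$grid
  hii <- build_hii(landscape$features, config, grid)
  richness <- stack_richness(lapply(landscape$habitat, binarize_habitat))
  rich90 <- resample(richness$normalized, grid, "bilinear")
  vdep <- normalize_inverse_vdep(landscape$vdep)
  vdep90 <- resample(vdep$normalized_inverse, grid, "bilinear")
  surface <- compute_lii(hii$hii, rich90, vdep90, radius = radius,
                         weights = weights)
  out <- list(hii = hii, richness = richness, vdep = vdep,
              lii = surface, landscape = landscape)
  if (planning) {
    out$corridors <- build_corridors(surface, landscape$priority,
                                     fraction = fraction)
    out$expansion <- expansion_areas(surface, out$corridors$priority_mask,
                                     threshold = threshold)
  }
  out
}

#' Summary statistics of an integrity surface
#'
#' Reproduces the model's evaluation design on any landscape: random points
#' across the valid extent, a one-way ANOVA of index values across ownership
#' classes (with Tukey HSD letters), and a Welch t-test of protected versus
#' unprotected samples.
#'
#' @param surface An `lii_surface` from [compute_lii()].
#' @param ownership [lii_raster()] of ownership class codes (or `NULL` to
#'   skip the ANOVA).
#' @param priority_mask Binary [lii_raster()] of protected priority areas (or
#'   `NULL` to skip the t-test).
#' @param n Points per stratum (default 50).
#' @param seed Sampling seed.
#' @param alpha Post-hoc familywise level (default 0.01).
#' @return List with `samples` (tibble), `anova` (`lii_anova`), `posthoc`
#'   (letter tibble), and `welch` (`lii_ttest`); absent parts are `NULL`.
#' @export
lii_stats <- function(surface, ownership = NULL, priority_mask = NULL,
                      n = 50, seed = 1, alpha = 0.01) {
  stopifnot(inherits(surface, "lii_surface"))
  r <- surface$values
  valid <- with_values(r, ifelse(is.na(r$values), NA_real_, 1))
  out <- list(samples = NULL, anova = NULL, posthoc = NULL, welch = NULL)
  samples <- list()
  if (!is.null(ownership)) {
    pts <- sample_points(valid, n, strata = ownership, seed = seed)
    pts <- extract_values(r, pts)
    groups <- split(pts$value, pts$stratum)
    out$anova <- one_way_anova(groups)
    out$posthoc <- pairwise_posthoc(groups, alpha = alpha)
    samples$ownership <- dplyr::mutate(pts, design = "ownership")
  }
  if (!is.null(priority_mask)) {
    prot <- with_values(priority_mask,
                        ifelse(is.na(r$values), NA_real_,
                               as.numeric(priority_mask$values == 1)))
    lab <- with_values(prot, matrix(
      ifelse(is.na(prot$values), NA_real_, prot$values),
      nrow(prot$values), ncol(prot$values)))
    pts <- sample_points(valid, n, strata = lab, seed = seed + 1)
    pts <- extract_values(r, pts)
    pts$stratum <- ifelse(pts$stratum == "1", "protected", "unprotected")
    out$welch <- welch_t_test(pts$value[pts$stratum == "protected"],
                              pts$value[pts$stratum == "unprotected"])
    samples$protection <- dplyr::mutate(pts, design = "protection")
  }
  if (length(samples)) out$samples <- dplyr::bind_rows(samples)
  out
}
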