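#' A species habitat-suitability model
#'
#' Wraps a categorical suitability raster (integer codes on the richness-model
#' grid, nominally 240 m) together with a species identifier and the declared
#' code set.
#'
#' @param species_id Species identifier (text).
#' @param suitability [lii_raster()] of categorical suitability codes.
#' @param code_set Integer codes that may appear in the raster
#'   (default `0:3`; 0 = no suitability).
#' @return An object of class `habitat_model`.
#' @export
habitat_model <- function(species_id, suitability, code_set = 0:3) {
  stopifnot(is.character(species_id), length(species_id) == 1,
            inherits(suitability, "lii_raster"))
  vals <- suitability$values[!is.na(suitability$values)]
  extra <- setdiff(unique(vals), code_set)
  if (length(extra)) {
    stop(sprintf("species '%s': suitability codes outside declared set: %s",
                 species_id, paste(extra, collapse = ", ")))
  }
  structure(list(species_id = species_id, suitability = suitability,
                 code_set = code_set),
            class = "habitat_model")
}

#' Binarize a habitat model to suitable / not suitable
#'
#' @param h A [habitat_model()].
#' @param suitable_codes Codes counted as suitable habitat. Default: every
#'   nonzero code in the model's declared set.
#' @return Binary [lii_raster()] (1 = suitable), nodata preserved.
#' @export
binarize_habitat <- function(h, suitable_codes = NULL) {
  stopifnot(inherits(h, "habitat_model"))
  if (is.null(suitable_codes)) suitable_codes <- setdiff(h$code_set, 0)
  if (!length(suitable_codes)) stop("suitable_codes must be non-empty")
  unknown <- setdiff(suitable_codes, h$code_set)
  if (length(unknown)) {
    stop(sprintf("unknown suitability code(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  v <- h$suitability$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v %in% suitable_codes))
  with_values(h$suitability, matrix(out, nrow(v), ncol(v)))
}

#' Stack binary habitat layers into a species-richness surface
#'
#' Cellwise sum of the binary layers gives the number of species with suitable
#' habitat per cell; the count surface is then min-max normalized to `[0, 1]`
#' over the observed range of valid cells. When every valid cell carries the
#' same count (no discriminating information) the normalized surface is a
#' neutral constant 0.5 and a warning is issued.
#'
#' @param binaries Non-empty list of binary [lii_raster()]s on one grid.
#' @return An object of class `richness_surface`: list with `counts` and
#'   `normalized` rasters and `n_species`.
#' @export
stack_richness <- function(binaries) {
  g <- check_shared_grid(binaries)
  counts <- binaries[[1]]$values
  for (b in binaries[-1]) counts <- counts + b$values
  valid <- !is.na(counts)
  if (!any(valid)) stop("no valid cells in richness stack")
  lo <- min(counts[valid]); hi <- max(counts[valid])
  if (hi > lo) {
    norm <- (counts - lo) / (hi - lo)
  } else {
    warning("uniform species richness: normalized surface set to constant 0.5")
    norm <- ifelse(valid, 0.5, NA_real_)
    norm <- matrix(norm, nrow(counts), ncol(counts))
  }
  structure(list(
    counts = lii_raster(counts, g),
    normalized = lii_raster(norm, g),
    n_species = length(binaries)
  ), class = "richness_surface")
}

#' @export
print.richness_surface <- function(x, ...) {
  v <- x$counts$values[!is.na(x$counts$values)]
  cat(sprintf("<richness_surface> %d species, counts %d-%d on %s\n",
              x$n_species, as.integer(min(v)), as.integer(max(v)),
              format(x$counts$grid)))
  invisible(x)
}

#' Normalized inverse vegetation departure
#'
#' Vegetation departure (VDEP) is a 0-100 measure of how far current
#' vegetation has departed from reference conditions. The integrity indicator
#' is its normalized inverse over the fixed theoretical range:
#' `(100 - VDEP) / 100`, so 0 means complete departure and 1 means none,
#' aligned with the low-high gradient of the other indicators.
#'
#' @param v [lii_raster()] of raw VDEP values in `[0, 100]`.
#' @return An object of class `vdep_surface`: list with `raw` and
#'   `normalized_inverse` rasters.
#' @export
normalize_inverse_vdep <- function(v) {
  stopifnot(inherits(v, "lii_raster"))
  vals <- v$values[!is.na(v$values)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 100)) {
    stop(sprintf("VDEP values outside [0, 100]: observed range [%g, %g]",
                 min(vals), max(vals)))
  }
  structure(list(
    raw = v,
    normalized_inverse = with_values(v, (100 - v$values) / 100)
  ), class = "vdep_surface")
}

#' @export
print.vdep_surface <- function(x, ...) {
  cat(sprintf("<vdep_surface> on %s\n", format(x$raw$grid)))
  invisible(x)
}
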