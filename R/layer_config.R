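#' Distance-decay parameters for one human-influence layer
#'
#' @param site_impact Intactness at distance 0, in `(0, 1]`; lower values
#'   denote greater site impact.
#' @param distance_m Distance of influence (m): the minimum distance at which
#'   intactness reaches 1.0. Must be > 0.
#' @param family Decay family, `"linear"` or `"logistic"`.
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(site_impact, distance_m, family) {
  if (!is.numeric(site_impact) || length(site_impact) != 1 ||
      is.na(site_impact) || site_impact <= 0 || site_impact > 1) {
    stop(sprintf("site_impact must be in (0, 1], got %s", site_impact))
  }
  if (!is.numeric(distance_m) || length(distance_m) != 1 ||
      is.na(distance_m) || distance_m <= 0) {
    stop(sprintf("distance_m must be > 0, got %s", distance_m))
  }
  family <- as.character(family)
  if (!family %in% c("linear", "logistic")) {
    stop(sprintf("unknown decay family '%s' (expected linear or logistic)", family))
  }
  structure(list(site_impact = as.numeric(site_impact),
                 distance_m = as.numeric(distance_m), family = family),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("<decay_params> s = %g, D = %g m, %s\n",
              x$site_impact, x$distance_m, x$family))
  invisible(x)
}

new_layer_config <- function(name, category, geometry_kind, decay,
                             source_path = NULL) {
  if (!category %in% c("transportation", "urban_industrial", "managed_landcover")) {
    stop(sprintf("layer '%s': unknown category '%s'", name, category))
  }
  if (!geometry_kind %in% c("point", "line", "polygon", "raster_mask")) {
    stop(sprintf("layer '%s': unknown geometry_kind '%s'", name, geometry_kind))
  }
  structure(list(name = name, category = category,
                 geometry_kind = geometry_kind, decay = decay,
                 source_path = source_path),
            class = "layer_config")
}

#' Load a human-influence layer configuration
#'
#' Reads a YAML configuration with one entry per modeled layer (name,
#' category, geometry kind, site impact score, distance of influence, decay
#' family, optional data source path). The shipped default configuration
#' ([default_layer_config()]) carries the full 16-layer parameterization of
#' the human-influence model. Distances of influence beyond the global
#' 4-km cap — the distance within which most reported effects of human
#' development on wildlife occur — are rejected unless
#' `allow_large_distance = TRUE`.
#'
#' @param path Path to a YAML config file.
#' @param max_distance_m Distance-of-influence cap in meters (default 4000).
#' @param allow_large_distance Permit layers beyond the cap.
#' @return A named list of `layer_config` objects, one per layer.
#' @export
load_layer_config <- function(path, max_distance_m = 4000,
                              allow_large_distance = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  doc <- yaml::read_yaml(path)
  entries <- doc$layers %||% doc
  if (!length(entries)) stop("config contains no layers")
  out <- list()
  for (e in entries) {
    for (f in c("name", "category", "geometry_kind", "site_impact",
                "distance_m", "decay")) {
      if (is.null(e[[f]])) {
        stop(sprintf("layer '%s': missing field '%s'",
                     e$name %||% "<unnamed>", f))
      }
    }
    if (e$name %in% names(out)) {
      stop(sprintf("duplicate layer name '%s' in config", e$name))
    }
    dp <- decay_params(e$site_impact, e$distance_m, e$decay)
    if (dp$distance_m > max_distance_m && !allow_large_distance) {
      stop(sprintf(
        "layer '%s': distance_m %g exceeds the %g m cap (set allow_large_distance = TRUE to override)",
        e$name, dp$distance_m, max_distance_m))
    }
    out[[e$name]] <- new_layer_config(e$name, e$category, e$geometry_kind, dp,
                                      e$source_path)
  }
  out
}

#' The shipped default 16-layer configuration
#'
#' @inheritParams load_layer_config
#' @return A named list of 16 `layer_config` objects covering the three
#'   transportation, eight urban/industrial and five managed-landcover inputs
#'   of the human-influence model.
#' @export
default_layer_config <- function(max_distance_m = 4000,
                                 allow_large_distance = FALSE) {
  path <- system.file("extdata", "hii_layers.yaml", package = "lii",
                      mustWork = TRUE)
  load_layer_config(path, max_distance_m, allow_large_distance)
}

#' Layer configuration as a tibble
#'
#' @param config A list of `layer_config` objects from [load_layer_config()].
#' @return A tibble with one row per layer: name, category, geometry kind,
#'   site impact, distance of influence, decay family.
#' @export
layer_config_table <- function(config) {
  tibble::tibble(
    name = unname(vapply(config, `[[`, character(1), "name")),
    category = unname(vapply(config, `[[`, character(1), "category")),
    geometry_kind = unname(vapply(config, `[[`, character(1), "geometry_kind")),
    site_impact = unname(vapply(config, function(l) l$decay$site_impact, numeric(1))),
    distance_m = unname(vapply(config, function(l) l$decay$distance_m, numeric(1))),
    decay = unname(vapply(config, function(l) l$decay$family, character(1)))
  )
}
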