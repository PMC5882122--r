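#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The on-disk format is the ESRI ASCII grid (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by cell values, north row first. The format has a single
#' `cellsize`, so square pixels are guaranteed by construction; a header
#' carrying separate `dx`/`dy` entries (the rectangular-pixel variant) is
#' rejected.
#'
#' @param path Path to an `.asc` file.
#' @param crs_id CRS identifier to attach (the format itself stores none).
#' @return An [lii_raster()]; nodata cells are `NA` in memory.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, crs_id = "local-m") {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop(sprintf("not an ASCII grid (too short): %s", path))
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- parts[2]
    i <- i + 1
  }
  if (any(c("dx", "dy") %in% names(hdr))) {
    stop("non-square pixels: dx/dy headers are not supported")
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("missing header field(s): %s",
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  }
  n_cols <- as.integer(hdr$ncols)
  n_rows <- as.integer(hdr$nrows)
  px <- as.numeric(hdr$cellsize)
  xll <- as.numeric(hdr$xllcorner %||% 0)
  yll <- as.numeric(hdr$yllcorner %||% 0)
  nodata <- as.numeric(hdr$nodata_value %||% -9999)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("expected %d values, found %d", n_rows * n_cols, length(vals)))
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- grid_spec(
    x_origin = xll, y_origin = yll + n_rows * px,
    pixel_size = px, n_rows = n_rows, n_cols = n_cols, crs_id = crs_id
  )
  lii_raster(m, grid, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so that
#' `read_raster(write_raster(r, p))` reproduces `r` bit-exactly for doubles.
#'
#' @param r An [lii_raster()].
#' @param path Destination path (`.asc` conventionally).
#' @return `path`, invisibly usable in pipes.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "lii_raster"))
  g <- r$grid
  m <- r$values
  m[is.na(m)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$x_origin),
    sprintf("yllcorner %.17g", g$y_origin - g$n_rows * g$pixel_size),
    sprintf("cellsize %.17g", g$pixel_size),
    sprintf("NODATA_value %.17g", r$nodata)
  )
  body <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  ok <- tryCatch(
    writeLines(c(hdr, body), path),
    error = function(e) stop(sprintf("cannot write raster to %s: %s",
                                     path, conditionMessage(e)))
  )
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- vector features ------------------------------------------------------

#' Build a feature collection
#'
#' Features are simple planar geometries in the shared projected CRS:
#' * point: a length-2 numeric `c(x, y)`
#' * line: a 2-column coordinate matrix (a polyline)
#' * polygon: a list of 2-column ring matrices; the first ring is the exterior,
#'   later rings are holes (even-odd rule)
#'
#' @param geoms List of geometries as above.
#' @param types Character vector, one of `"point"`, `"line"`, `"polygon"` per
#'   geometry.
#' @param attrs Optional tibble of per-feature attributes.
#' @return An object of class `lii_features`.
#' @export
lii_features <- function(geoms = list(), types = character(),
                         attrs = NULL) {
  if (length(geoms) != length(types)) stop("geoms and types lengths differ")
  bad <- setdiff(unique(types), c("point", "line", "polygon"))
  if (length(bad)) stop(sprintf("unknown geometry type(s): %s",
                                paste(bad, collapse = ", ")))
  if (is.null(attrs)) attrs <- tibble::tibble(.rows = length(geoms))
  structure(list(geoms = geoms, types = types, attrs = tibble::as_tibble(attrs)),
            class = "lii_features")
}

#' @export
print.lii_features <- function(x, ...) {
  cat(sprintf("<lii_features> %d feature(s): %s\n", length(x$geoms),
              paste(sprintf("%d %s", table(factor(x$types,
                c("point", "line", "polygon"))),
                c("point", "line", "polygon")), collapse = ", ")))
  invisible(x)
}

#' @export
length.lii_features <- function(x) length(x$geoms)

#' Read features from a GeoJSON file
#'
#' Supports `Point`, `MultiPoint`, `LineString`, `MultiLineString`, `Polygon`
#' and `MultiPolygon` geometries in a `FeatureCollection` (or a bare geometry /
#' `Feature`). Multi-part geometries are flattened into one feature per part,
#' each part inheriting the feature's properties. Coordinates must already be
#' in a planar projected CRS in meters; no reprojection is attempted.
#'
#' @param path Path to a `.geojson` / `.json` file.
#' @return An [lii_features()] collection; properties become `attrs`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("GeoJSON file not found: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(gj$type %||% "",
    FeatureCollection = gj$features,
    Feature = list(gj),
    Point = , MultiPoint = , LineString = , MultiLineString = ,
    Polygon = , MultiPolygon = list(list(geometry = gj, properties = NULL)),
    stop(sprintf("unsupported GeoJSON type: %s", gj$type %||% "<missing>"))
  )
  geoms <- list(); types <- character(); props <- list()
  coord_mat <- function(cc) {
    do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  }
  for (f in feats) {
    geom <- f$geometry
    p <- f$properties
    add <- function(g, t) {
      geoms[[length(geoms) + 1]] <<- g
      types[[length(types) + 1]] <<- t
      props[[length(props) + 1]] <<- p
    }
    switch(geom$type,
      Point = add(c(as.numeric(geom$coordinates[[1]]),
                    as.numeric(geom$coordinates[[2]])), "point"),
      MultiPoint = for (c1 in geom$coordinates)
        add(c(as.numeric(c1[[1]]), as.numeric(c1[[2]])), "point"),
      LineString = add(coord_mat(geom$coordinates), "line"),
      MultiLineString = for (part in geom$coordinates)
        add(coord_mat(part), "line"),
      Polygon = add(lapply(geom$coordinates, coord_mat), "polygon"),
      MultiPolygon = for (part in geom$coordinates)
        add(lapply(part, coord_mat), "polygon"),
      stop(sprintf("unsupported geometry type: %s", geom$type))
    )
  }
  attrs <- props_to_tibble(props)
  lii_features(geoms, types, attrs)
}

props_to_tibble <- function(props) {
  keys <- unique(unlist(lapply(props, names)))
  if (is.null(keys) || !length(keys)) return(tibble::tibble(.rows = length(props)))
  cols <- lapply(keys, function(k) {
    vapply(props, function(p) {
      v <- p[[k]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  names(cols) <- keys
  out <- tibble::as_tibble(cols)
  # coerce purely numeric columns back
  for (k in keys) {
    suppressWarnings(num <- as.numeric(out[[k]]))
    if (!anyNA(num[!is.na(out[[k]])])) out[[k]] <- num
  }
  out
}

#' Write features to a GeoJSON file
#'
#' @param features An [lii_features()] collection.
#' @param path Destination path.
#' @return `path`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "lii_features"))
  n <- length(features$geoms)
  attrs <- features$attrs
  mk_coords <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  feats <- lapply(seq_len(n), function(i) {
    g <- features$geoms[[i]]
    geom <- switch(features$types[i],
      point = list(type = "Point", coordinates = c(g[1], g[2])),
      line = list(type = "LineString", coordinates = mk_coords(g)),
      polygon = list(type = "Polygon", coordinates = lapply(g, mk_coords))
    )
    p <- if (ncol(attrs)) as.list(attrs[i, ]) else stats::setNames(list(), character())
    list(type = "Feature", geometry = geom, properties = p)
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}
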