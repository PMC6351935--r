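# cli_reporting I/O: GeoJSON readers/writers for the layer types the
# pipeline consumes (LineString segments, Point tables, Polygon DAs), plus
# full-precision CSV helpers. Only planar coordinates in metres are
# accepted; geographic (degree) coordinates are rejected at load time.

check_planar <- function(coords, what) {
  if (!length(coords)) return(invisible())
  xs <- coords[, 1L]; ys <- coords[, 2L]
  if (all(abs(xs) <= 360) && all(abs(ys) <= 90))
    stopf("%s: coordinates look geographic (degrees); reproject to a planar CRS in metres",
          what)
  invisible()
}

to_geojson_txt <- function(features) {
  jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                   auto_unbox = TRUE, digits = NA, na = "null",
                   null = "null", pretty = FALSE)
}

#' Write a segment layer as GeoJSON LineStrings
#'
#' @param segments A [geo_segments()] layer.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_segments_geojson <- function(segments, path) {
  features <- lapply(seq_len(nrow(segments)), function(i) {
    list(type = "Feature",
         properties = list(id = segments$id[i], mode = segments$mode[i],
                           class_label = segments$class_label[i],
                           speed_kmh = segments$speed_kmh[i]),
         geometry = list(type = "LineString",
                         coordinates = segments$coords[[i]]))
  })
  writeLines(to_geojson_txt(features), path)
  invisible(path)
}

feature_coords_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

prop_or_na <- function(props, name, cast = as.character) {
  v <- props[[name]]
  if (is.null(v)) cast(NA) else cast(v)
}

#' Read a segment layer from GeoJSON
#'
#' Accepts LineString and MultiLineString features with properties `mode`,
#' optional `class_label` and `speed_kmh`. Road features must carry a
#' `class_label`.
#'
#' @param path GeoJSON file.
#' @return A [geo_segments()] layer.
#' @export
read_segments_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (!length(feats)) return(empty_segments())
  coords <- list(); mode <- character(0); cls <- character(0)
  spd <- numeric(0); ids <- character(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    fid <- prop_or_na(props, "id")
    if (is.na(fid)) fid <- sprintf("feat_%d", k)
    fmode <- prop_or_na(props, "mode")
    if (is.na(fmode))
      stopf("feature '%s' in %s: missing required property `mode`", fid, path)
    fcls <- prop_or_na(props, "class_label")
    if (fmode == "road" && is.na(fcls))
      stopf("feature '%s' in %s: road is missing required property `class_label`",
            fid, path)
    geoms <- switch(f$geometry$type,
      LineString = list(f$geometry$coordinates),
      MultiLineString = f$geometry$coordinates,
      stopf("feature '%s' in %s: unsupported geometry %s", fid, path,
            f$geometry$type))
    for (gi in seq_along(geoms)) {
      coords[[length(coords) + 1L]] <- feature_coords_matrix(geoms[[gi]])
      mode <- c(mode, fmode)
      cls <- c(cls, fcls)
      spd <- c(spd, prop_or_na(props, "speed_kmh", as.numeric))
      ids <- c(ids, if (length(geoms) > 1L) sprintf("%s#%d", fid, gi) else fid)
    }
  }
  check_planar(do.call(rbind, coords), path)
  geo_segments(coords, mode = mode, class_label = cls, speed_kmh = spd,
               id = ids)
}

#' Write a point table as GeoJSON
#'
#' @param df Data frame with coordinate columns `x`, `y`; every other column
#'   becomes a feature property.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_points_geojson <- function(df, path) {
  prop_cols <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, prop_cols, drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  writeLines(to_geojson_txt(features), path)
  invisible(path)
}

#' Read a point table from GeoJSON
#' @param path GeoJSON file of Point features.
#' @return Data frame with `x`, `y`, and one column per property.
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (!length(feats)) return(data.frame(x = numeric(0), y = numeric(0)))
  rows <- lapply(feats, function(f) {
    stopifnot(f$geometry$type == "Point")
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      props)
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  check_planar(as.matrix(out[, c("x", "y")]), path)
  rownames(out) <- NULL
  out
}

#' Write dissemination areas as GeoJSON polygons
#'
#' @param das DA table from [generate_city()] (columns `id`, `x`, `y`,
#'   `population`, `area_km2`, list-column `polygon`).
#' @param path Output file.
#' @param extra Optional data frame of per-DA properties to attach (matched
#'   by `location_id`/`id`), e.g. SPAR values for an access surface.
#' @return Invisibly, `path`.
#' @export
write_das_geojson <- function(das, path, extra = NULL) {
  features <- lapply(seq_len(nrow(das)), function(i) {
    props <- list(id = das$id[i], population = das$population[i],
                  area_km2 = das$area_km2[i],
                  centroid_x = das$x[i], centroid_y = das$y[i])
    if (!is.null(extra)) {
      j <- match(das$id[i], extra$location_id %||% extra$id)
      for (nm in setdiff(names(extra), c("location_id", "id")))
        props[[nm]] <- extra[[nm]][j]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(das$polygon[[i]])))
  })
  writeLines(to_geojson_txt(features), path)
  invisible(path)
}

#' Read dissemination areas from GeoJSON polygons
#' @param path GeoJSON file written by [write_das_geojson()].
#' @return DA data frame with `polygon` list-column.
#' @export
read_das_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  rows <- vector("list", length(feats))
  polys <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    stopifnot(f$geometry$type == "Polygon")
    p <- f$properties
    rows[[k]] <- data.frame(id = p$id, x = p$centroid_x, y = p$centroid_y,
                            population = p$population,
                            area_km2 = p$area_km2, stringsAsFactors = FALSE)
    polys[[k]] <- feature_coords_matrix(f$geometry$coordinates[[1]])
  }
  out <- do.call(rbind, rows)
  out$polygon <- polys
  check_planar(do.call(rbind, polys), path)
  out
}

# full-precision CSV: numbers survive a write/read round trip exactly
write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE)
}

#' Write a city bundle to a directory of GeoJSON/CSV files
#'
#' One GeoJSON file per layer plus `covariates.csv` and `config.json`.
#' Deterministic: identical bundles produce byte-identical files.
#'
#' @param bundle A `city_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_city_geojson <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_segments_geojson(bundle$roads, p("roads.geojson"))
  write_segments_geojson(bundle$sidewalks, p("sidewalks.geojson"))
  if (nrow(bundle$trails)) write_segments_geojson(bundle$trails,
                                                  p("trails.geojson"))
  write_points_geojson(bundle$intersections, p("intersections.geojson"))
  write_segments_geojson(bundle$bus_routes, p("bus_routes.geojson"))
  write_points_geojson(bundle$bus_stops, p("bus_stops.geojson"))
  write_segments_geojson(bundle$train_lines, p("train_lines.geojson"))
  write_points_geojson(bundle$stations, p("stations.geojson"))
  write_das_geojson(bundle$das, p("das.geojson"))
  write_points_geojson(bundle$clinics, p("clinics.geojson"))
  write_csv_full(bundle$covariates, p("covariates.csv"))
  writeLines(jsonlite::toJSON(unclass(bundle$config), auto_unbox = TRUE,
                              digits = NA),
             p("config.json"))
  invisible(dir)
}

#' Read a city bundle from a directory written by [write_city_geojson()]
#'
#' @param dir Directory of layer files.
#' @return A `city_bundle`.
#' @export
read_layers <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("roads.geojson", "sidewalks.geojson", "das.geojson",
            "clinics.geojson")
  missing <- need[!file.exists(p(need))]
  if (length(missing))
    stopf("missing layer file(s) in %s: %s", dir,
          paste(missing, collapse = ", "))
  cfg <- NULL
  if (file.exists(p("config.json"))) {
    raw <- jsonlite::fromJSON(p("config.json"))
    cfg <- do.call(city_config, raw[names(formals(city_config))])
  }
  covariates <- NULL
  if (file.exists(p("covariates.csv"))) {
    covariates <- utils::read.csv(p("covariates.csv"), check.names = FALSE,
                                  stringsAsFactors = FALSE)
  }
  structure(list(
    config = cfg,
    roads = read_segments_geojson(p("roads.geojson")),
    sidewalks = read_segments_geojson(p("sidewalks.geojson")),
    trails = if (file.exists(p("trails.geojson")))
      read_segments_geojson(p("trails.geojson")) else empty_segments(),
    intersections = read_points_geojson(p("intersections.geojson")),
    bus_routes = if (file.exists(p("bus_routes.geojson")))
      read_segments_geojson(p("bus_routes.geojson")) else empty_segments(),
    bus_stops = if (file.exists(p("bus_stops.geojson")))
      read_points_geojson(p("bus_stops.geojson")) else NULL,
    train_lines = if (file.exists(p("train_lines.geojson")))
      read_segments_geojson(p("train_lines.geojson")) else empty_segments(),
    stations = if (file.exists(p("stations.geojson")))
      read_points_geojson(p("stations.geojson")) else NULL,
    das = read_das_geojson(p("das.geojson")),
    clinics = read_points_geojson(p("clinics.geojson")),
    covariates = covariates), class = "city_bundle")
}
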