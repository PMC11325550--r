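# Readers and writers for the pipeline's exchange formats:
# CSV mobile readings and aggregates, GeoJSON geometry layers, and the
# feature-table CSV with its sidecar column-schema JSON.

#' Read mobile monitoring readings from CSV
#'
#' Expected columns: `reading_id,time,lon,lat,pollutant,value`. Times are
#' parsed as UTC; a `drive_day` column (calendar date of `time`) is added.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of readings with a `drive_day` Date column.
#' @export
read_mobile_readings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reading_id", "time", "lon", "lat", "pollutant", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("readings CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) stop("non-numeric value at line ", bad[1] + 1L)
  df$value <- as.numeric(df$value)
  df$time <- as.POSIXct(df$time, tz = "UTC")
  df$drive_day <- as.Date(df$time, tz = "UTC")
  df
}

#' Write per-segment aggregates to CSV
#'
#' @param agg Data.frame from [mean_of_means()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregates <- function(agg, path) {
  utils::write.csv(agg, path, row.names = FALSE)
  invisible(path)
}

#' Read road segments from GeoJSON
#'
#' A FeatureCollection of LineStrings with properties `segment_id` and
#' `city_id`. Coordinates are WGS84 lon/lat.
#'
#' @param path Path to a GeoJSON file.
#' @return A list with `segment_id`, `city_id`, and `geometry` (a list of
#'   two-column lon/lat matrices), of class `"road_segments"`.
#' @export
read_segments_geojson <- function(path) {
  if (!file.exists(path)) stop("segments file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  ids <- character(length(feats))
  city <- character(length(feats))
  geom <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "LineString"))
      stop("segment feature ", i, " is not a LineString")
    ids[i] <- as.character(f$properties$segment_id)
    city[i] <- as.character(f$properties$city_id %||% NA_character_)
    geom[[i]] <- do.call(rbind, lapply(f$geometry$coordinates,
                                       function(p) c(p[[1]], p[[2]])))
  }
  if (anyDuplicated(paste(city, ids)))
    stop("duplicate segment_id within a city")
  structure(list(segment_id = ids, city_id = city, geometry = geom),
            class = "road_segments")
}

#' Write road segments to GeoJSON
#'
#' @param segments A `"road_segments"` list as returned by
#'   [read_segments_geojson()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(seq_along(segments$segment_id), function(i) {
    list(type = "Feature",
         properties = list(segment_id = segments$segment_id[i],
                           city_id = segments$city_id[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(segments$geometry[[i]])),
                                              function(j) as.numeric(segments$geometry[[i]][j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygon layers (land use, population cells) from GeoJSON
#'
#' A FeatureCollection of Polygons; only the outer ring is used. All feature
#' properties are carried through.
#'
#' @param path Path to a GeoJSON file.
#' @return A list with `properties` (data.frame) and `rings` (list of
#'   two-column lon/lat matrices).
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("polygon file not found: ", path)
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  rings <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature ", i, " is not a Polygon")
    ring <- f$geometry$coordinates[[1]]
    rings[[i]] <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    props[[i]] <- f$properties
  }
  props <- do.call(rbind, lapply(props, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  list(properties = props, rings = rings)
}

#' Write a feature table to CSV (lossless round trip)
#'
#' Numeric values are written with 17 significant digits so that
#' write-then-read reproduces the table bitwise. A sidecar JSON schema
#' describing each column is written next to the CSV.
#'
#' @param ft A feature table: data.frame with a `segment_id` column and
#'   numeric predictor columns.
#' @param path Output CSV path; the schema goes to `paste0(path, ".schema.json")`.
#' @param schema Optional named list describing columns (class, buffer,
#'   statistic); stored as-is in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, schema = NULL) {
  stopifnot("segment_id" %in% names(ft))
  num <- vapply(ft, is.numeric, logical(1))
  out <- ft
  out[num] <- lapply(ft[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (is.null(schema))
    schema <- lapply(names(ft)[num], function(nm) list(column = nm))
  jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data.frame with `segment_id` (character) and numeric columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(segment_id = "character"))
  for (nm in setdiff(names(df), "segment_id")) df[[nm]] <- as.numeric(df[[nm]])
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
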