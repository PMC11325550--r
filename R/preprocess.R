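# Mobile-monitoring preprocessing: range filtering of unrealistic 1-s values,
# campaign-wide winsorizing, additive temporal correction against a routine
# reference site (NO2 only), snapping of GPS points to ~50 m road segments,
# and per-segment "mean of means" aggregation over drive days.

.pollutant_bounds <- list(
  NO2 = c(0, 500),        # ug/m3
  UFP = c(250, 500000)    # particles/cm3
)

#' Remove physically unrealistic 1-Hz readings
#'
#' NO2 readings outside \[0, 500\] ug/m3 and UFP readings outside
#' \[250, 500000\] particles/cm3 are dropped; bounds are inclusive and the
#' input order is preserved.
#'
#' @param readings Data.frame of mobile readings with a numeric `value` column.
#' @param pollutant `"NO2"` or `"UFP"`.
#' @return The filtered data.frame.
#' @export
filter_range <- function(readings, pollutant) {
  b <- .pollutant_bounds[[pollutant]]
  if (is.null(b)) stop("unknown pollutant: ", pollutant,
                       " (expected NO2 or UFP)")
  keep <- is.finite(readings$value) & readings$value >= b[1] & readings$value <= b[2]
  readings[keep, , drop = FALSE]
}

#' Winsorize a vector at the 2.5th and 97.5th percentiles
#'
#' Values above the 97.5th percentile are set to the 97.5th-percentile value
#' and values below the 2.5th percentile to the 2.5th-percentile value.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) computed on the input vector itself.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param probs Lower/upper tail probabilities, default `c(0.025, 0.975)`.
#' @return Vector of the same length with tails clamped.
#' @export
winsorize <- function(values, probs = c(0.025, 0.975)) {
  if (length(values) == 0) stop("winsorize: empty vector")
  if (sum(is.finite(values)) < 2) stop("winsorize: need >= 2 finite values")
  q <- stats::quantile(values, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  pmin(pmax(values, q[1]), q[2])
}

#' Temporally correct NO2 readings against a reference-site series
#'
#' Each reading is adjusted additively for the hour it was taken:
#' `value - (reference value in that hour - campaign-wide reference mean)`.
#' UFP readings pass through unchanged (no routine UFP reference exists).
#'
#' @param readings Data.frame of readings with `time` (POSIXct, UTC),
#'   `pollutant` and `value` columns.
#' @param reference Data.frame with columns `hour` (POSIXct, UTC, truncated to
#'   the hour) and `value`: the routine-site hourly series covering the
#'   campaign.
#' @param method `"additive"` (default) or `"none"`.
#' @return The readings with corrected NO2 values.
#' @export
temporal_correct <- function(readings, reference, method = c("additive", "none")) {
  method <- match.arg(method)
  if (method == "none") return(readings)
  is_no2 <- readings$pollutant == "NO2"
  if (!any(is_no2)) return(readings)
  ref_hour <- as.POSIXct(trunc(reference$hour, units = "hours"), tz = "UTC")
  rd_hour <- as.POSIXct(trunc(readings$time[is_no2], units = "hours"), tz = "UTC")
  idx <- match(as.numeric(rd_hour), as.numeric(ref_hour))
  if (anyNA(idx)) {
    missing_hours <- unique(format(rd_hour[is.na(idx)], "%Y-%m-%d %H:00",
                                   tz = "UTC"))
    stop("temporal_correct: reference series missing hour(s): ",
         paste(utils::head(missing_hours, 5), collapse = ", "))
  }
  deviation <- reference$value[idx] - mean(reference$value)
  readings$value[is_no2] <- readings$value[is_no2] - deviation
  readings
}

#' Snap readings to their nearest road segment
#'
#' Each reading is assigned to the segment minimizing perpendicular distance
#' to the segment polyline; readings farther than `max_snap_m` from every
#' segment are dropped. Distance ties are broken by the smallest
#' `segment_id`.
#'
#' @param readings Data.frame of readings with `lon`/`lat` (WGS84) or
#'   projected `x`/`y` columns.
#' @param segments A `"road_segments"` object ([read_segments_geojson()]) or a
#'   list with `segment_id` and `geometry` (list of two-column matrices) in
#'   the same coordinate system as the readings.
#' @param max_snap_m Maximum snap distance in meters (default 35: half a 50 m
#'   segment plus GPS error).
#' @param origin Projection reference `c(lon, lat)`; defaults to the mean
#'   reading position. Ignored when `x`/`y` are supplied.
#' @return The retained readings with `segment_id` and `snap_dist_m` columns.
#' @export
snap_to_segments <- function(readings, segments, max_snap_m = 35, origin = NULL) {
  if (length(segments$segment_id) == 0) stop("snap_to_segments: empty segment set")
  ord <- order(segments$segment_id)   # tie-break: smallest id wins on equality
  seg_ids <- segments$segment_id[ord]
  geoms <- segments$geometry[ord]
  if (all(c("x", "y") %in% names(readings))) {
    pts <- cbind(readings$x, readings$y)
    proj_geoms <- geoms
  } else {
    if (is.null(origin)) origin <- c(mean(readings$lon), mean(readings$lat))
    pts <- project_local(readings$lon, readings$lat, origin)
    proj_geoms <- lapply(geoms, function(g) project_local(g[, 1], g[, 2], origin))
  }
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_id <- rep(NA_character_, n)
  for (k in seq_along(proj_geoms)) {
    d <- .dist_points_polyline(pts, proj_geoms[[k]])
    better <- d < best   # strict: earlier (smaller) id kept on ties
    best[better] <- d[better]
    best_id[better] <- seg_ids[k]
  }
  keep <- best <= max_snap_m
  out <- readings[keep, , drop = FALSE]
  out$segment_id <- best_id[keep]
  out$snap_dist_m <- best[keep]
  out
}

#' Aggregate snapped readings to per-segment mean-of-means values
#'
#' Per segment, the mean of readings within each drive day is computed first,
#' then the unweighted mean over those daily means ("mean of means"). The
#' number of distinct drive days is the drive-pass count.
#'
#' @param snapped Data.frame with `segment_id`, `drive_day`, `value` and
#'   optionally `pollutant` columns.
#' @return Data.frame with columns `segment_id`, `pollutant`, `value`,
#'   `n_drive_pass`, `n_points`, one row per segment.
#' @export
mean_of_means <- function(snapped) {
  if (nrow(snapped) == 0) {
    return(data.frame(segment_id = character(), pollutant = character(),
                      value = numeric(), n_drive_pass = integer(),
                      n_points = integer(), stringsAsFactors = FALSE))
  }
  pol <- if ("pollutant" %in% names(snapped)) snapped$pollutant else NA_character_
  day_key <- paste(snapped$segment_id, snapped$drive_day, sep = "\r")
  daily <- tapply(snapped$value, day_key, mean)
  npts_day <- tapply(snapped$value, day_key, length)
  seg_of_day <- sub("\r.*$", "", names(daily))
  value <- tapply(daily, seg_of_day, mean)
  n_pass <- tapply(daily, seg_of_day, length)
  n_points <- tapply(npts_day, seg_of_day, sum)
  ids <- names(value)
  pol_per_seg <- if (all(is.na(pol))) NA_character_ else
    vapply(ids, function(s) pol[snapped$segment_id == s][1], character(1))
  data.frame(segment_id = ids,
             pollutant = unname(pol_per_seg),
             value = as.numeric(value),
             n_drive_pass = as.integer(n_pass),
             n_points = as.integer(n_points),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full preprocessing pipeline for one campaign
#'
#' Applies, in order: range filter, campaign-wide winsorizing, temporal
#' correction (NO2), segment snapping, and mean-of-means aggregation.
#'
#' @param readings Raw readings data.frame (see [read_mobile_readings()]).
#' @param segments Road segments (see [snap_to_segments()]).
#' @param pollutant `"NO2"` or `"UFP"`.
#' @param reference Optional hourly reference series for temporal correction.
#' @param max_snap_m Snap threshold in meters.
#' @param temporal Correction method, `"additive"` or `"none"`.
#' @return A list with `aggregates` (data.frame) and `provenance` (counts of
#'   readings removed/retained at each stage).
#' @export
preprocess_campaign <- function(readings, segments, pollutant,
                                reference = NULL, max_snap_m = 35,
                                temporal = c("additive", "none")) {
  temporal <- match.arg(temporal)
  n0 <- nrow(readings)
  readings <- readings[readings$pollutant == pollutant, , drop = FALSE]
  n_pol <- nrow(readings)
  filtered <- filter_range(readings, pollutant)
  n_filter <- nrow(filtered)
  filtered$value <- winsorize(filtered$value)
  if (!is.null(reference) && temporal == "additive" && pollutant == "NO2")
    filtered <- temporal_correct(filtered, reference)
  snapped <- snap_to_segments(filtered, segments, max_snap_m = max_snap_m)
  agg <- mean_of_means(snapped)
  list(aggregates = agg,
       provenance = list(n_input = n0, n_pollutant = n_pol,
                         removed_range_filter = n_pol - n_filter,
                         removed_snap = n_filter - nrow(snapped),
                         n_segments = nrow(agg)))
}
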