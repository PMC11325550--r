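# Buffer-based predictor extraction per road segment: land-use areas within
# circular buffers, traffic variables from the road network (nearest-road and
# in-buffer, total and heavy-duty, all and major roads), and area-weighted
# population. Buffers are centered on the segment midpoint. The same
# extraction applied to every city guarantees a shared column set, which the
# covariance-alignment step requires.

#' Land-use classes of the standard predictor set
#' @export
LANDUSE_CLASSES <- c("agricultural", "airport", "industry", "natural", "port",
                     "residential", "transportation", "urban_green", "water")

#' Default buffer radii (meters) for land-use and population features
#' @export
LANDUSE_BUFFERS <- c(100, 300, 500, 1000, 5000)

#' Default buffer radii (meters) for traffic features
#' @export
TRAFFIC_BUFFERS <- c(25, 50, 100, 300, 500, 1000)

#' Land-use area features within circular buffers
#'
#' For each segment midpoint, each land-use class and each buffer radius, the
#' intersected polygon area (m^2) within the buffer.
#'
#' @param midpoints n x 2 matrix of segment midpoints (projected meters).
#' @param landuse List with `rings` (list of two-column matrices, projected
#'   meters) and `class` (character, one of [LANDUSE_CLASSES] per ring).
#' @param classes Classes to compute; default all nine.
#' @param buffers_m Buffer radii in meters.
#' @return Numeric matrix, one column per `class_buffer` combination.
#' @export
buffer_area_features <- function(midpoints, landuse,
                                 classes = LANDUSE_CLASSES,
                                 buffers_m = LANDUSE_BUFFERS) {
  unknown <- setdiff(unique(landuse$class), LANDUSE_CLASSES)
  if (length(unknown))
    stop("unknown land-use class(es): ", paste(unknown, collapse = ", "))
  n <- nrow(midpoints)
  cols <- as.vector(outer(classes, buffers_m, paste, sep = "_"))
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (cl in classes) {
    rings <- landuse$rings[landuse$class == cl]
    if (!length(rings)) next
    for (r in buffers_m) {
      col <- paste(cl, r, sep = "_")
      for (i in seq_len(n)) {
        a <- 0
        for (ring in rings) a <- a + disk_polygon_area(ring, midpoints[i, ], r)
        out[i, col] <- a
      }
    }
  }
  out
}

#' Traffic features from the road network
#'
#' Per segment midpoint: traffic intensity (vehicles/day) on the nearest road
#' and nearest major road, their heavy-duty variants, and per buffer radius
#' the summed road length (all/major roads) plus length-weighted intensity
#' sums (intensity x road length within the buffer; all/major, total and
#' heavy-duty).
#'
#' @param midpoints n x 2 matrix of segment midpoints (projected meters).
#' @param roads List with `lines` (list of two-column matrices, meters),
#'   `intensity`, `hd_intensity` (vehicles/day) and `major` (logical).
#' @param buffers_m Buffer radii in meters.
#' @return Numeric matrix of traffic predictor columns.
#' @export
traffic_features <- function(midpoints, roads, buffers_m = TRAFFIC_BUFFERS) {
  n <- nrow(midpoints)
  m <- length(roads$lines)
  if (m == 0) stop("traffic_features: empty road network")
  has_major <- any(roads$major)
  if (!has_major)
    warning("road network has no major roads; nearest-major features set to 0")
  dmat <- matrix(Inf, n, m)
  for (k in seq_len(m))
    dmat[, k] <- .dist_points_polyline(midpoints, roads$lines[[k]])
  nearest <- apply(dmat, 1, which.min)
  cols <- c("traffic_nearest", "traffic_nearest_major",
            "hd_traffic_nearest", "hd_traffic_nearest_major",
            as.vector(outer(c("roadlength", "roadlength_major",
                              "traffic", "traffic_major",
                              "hd_traffic", "hd_traffic_major"),
                            buffers_m, paste, sep = "_")))
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  out[, "traffic_nearest"] <- roads$intensity[nearest]
  out[, "hd_traffic_nearest"] <- roads$hd_intensity[nearest]
  if (has_major) {
    dmaj <- dmat[, roads$major, drop = FALSE]
    maj_idx <- which(roads$major)
    nearest_maj <- maj_idx[apply(dmaj, 1, which.min)]
    out[, "traffic_nearest_major"] <- roads$intensity[nearest_maj]
    out[, "hd_traffic_nearest_major"] <- roads$hd_intensity[nearest_maj]
  }
  for (r in buffers_m) {
    for (i in seq_len(n)) {
      len <- numeric(m)
      for (k in seq_len(m)) {
        if (min(dmat[i, k]) > r) next
        len[k] <- disk_polyline_length(roads$lines[[k]], midpoints[i, ], r)
      }
      inb <- len > 0
      out[i, paste0("roadlength_", r)] <- sum(len)
      out[i, paste0("traffic_", r)] <- sum(len * roads$intensity)
      out[i, paste0("hd_traffic_", r)] <- sum(len * roads$hd_intensity)
      if (has_major) {
        mj <- roads$major
        out[i, paste0("roadlength_major_", r)] <- sum(len[mj])
        out[i, paste0("traffic_major_", r)] <- sum(len[mj] * roads$intensity[mj])
        out[i, paste0("hd_traffic_major_", r)] <- sum(len[mj] * roads$hd_intensity[mj])
      }
    }
  }
  out
}

#' Area-weighted population within circular buffers
#'
#' Each grid cell contributes its count times the fraction of its area inside
#' the buffer.
#'
#' @param midpoints n x 2 matrix of segment midpoints (projected meters).
#' @param population List with `rings` (list of cell polygons, meters) and
#'   `count` (persons per cell).
#' @param buffers_m Buffer radii in meters.
#' @return Numeric matrix with one `population_<r>` column per radius.
#' @export
population_features <- function(midpoints, population,
                                buffers_m = LANDUSE_BUFFERS) {
  n <- nrow(midpoints)
  cols <- paste0("population_", buffers_m)
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  m <- length(population$rings)
  if (m == 0) return(out)
  cell_area <- vapply(population$rings, .polygon_area, numeric(1))
  for (r in buffers_m) {
    col <- paste0("population_", r)
    for (i in seq_len(n)) {
      tot <- 0
      for (k in seq_len(m)) {
        if (cell_area[k] == 0) next
        a <- disk_polygon_area(population$rings[[k]], midpoints[i, ], r)
        if (a > 0) tot <- tot + population$count[k] * a / cell_area[k]
      }
      out[i, col] <- tot
    }
  }
  out
}

#' Build the full per-segment feature table
#'
#' Concatenates land-use, traffic and population feature groups for one city.
#' The column order is fully determined by the configuration, so two cities
#' built with the same configuration have identical column sets.
#'
#' @param segments A `"road_segments"` object (WGS84 geometry).
#' @param layers List with elements `landuse`, `roads`, `population`, each in
#'   WGS84 lon/lat with the structure the group functions expect
#'   (rings/lines as lon/lat matrices).
#' @param origin Projection reference `c(lon, lat)`; default: mean of segment
#'   midpoints.
#' @param landuse_buffers,traffic_buffers Buffer radii (meters).
#' @return Data.frame: `segment_id` plus numeric predictor columns, of class
#'   `c("feature_table", "data.frame")`.
#' @export
build_feature_table <- function(segments, layers, origin = NULL,
                                landuse_buffers = LANDUSE_BUFFERS,
                                traffic_buffers = TRAFFIC_BUFFERS) {
  mids_ll <- t(vapply(segments$geometry, .polyline_midpoint, numeric(2)))
  if (is.null(origin)) origin <- c(mean(mids_ll[, 1]), mean(mids_ll[, 2]))
  mids <- project_local(mids_ll[, 1], mids_ll[, 2], origin)
  proj_rings <- function(rs) lapply(rs, function(g)
    project_local(g[, 1], g[, 2], origin))
  blocks <- list()
  if (!is.null(layers$landuse)) {
    lu <- layers$landuse
    lu$rings <- proj_rings(lu$rings)
    blocks$landuse <- buffer_area_features(mids, lu, buffers_m = landuse_buffers)
  }
  if (!is.null(layers$roads)) {
    rd <- layers$roads
    rd$lines <- proj_rings(rd$lines)
    blocks$traffic <- traffic_features(mids, rd, buffers_m = traffic_buffers)
  }
  if (!is.null(layers$population)) {
    pop <- layers$population
    pop$rings <- proj_rings(pop$rings)
    blocks$population <- population_features(mids, pop, buffers_m = landuse_buffers)
  }
  ft <- data.frame(segment_id = segments$segment_id,
                   do.call(cbind, blocks), stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(ft) <- sub("^(landuse|traffic|population)\\.", "", names(ft))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Check that feature tables share an identical column set
#'
#' @param tables Named list of feature tables (one per city).
#' @return `TRUE` invisibly; errors naming differing columns otherwise.
#' @export
check_feature_columns <- function(tables) {
  ref <- setdiff(names(tables[[1]]), "segment_id")
  for (nm in names(tables)[-1]) {
    cols <- setdiff(names(tables[[nm]]), "segment_id")
    extra <- setdiff(cols, ref)
    miss <- setdiff(ref, cols)
    if (length(extra) || length(miss))
      stop("feature columns differ for ", nm,
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}
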