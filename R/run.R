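# Configuration-driven pipeline runners tying the modules together:
# simulate -> preprocess -> fit/transfer -> evaluate. Each runner is a thin
# wrapper over the package functions, reads a flat YAML (or list) config,
# and stamps its outputs with the seed and a hash of the configuration so
# any result can be reproduced from config + seed alone.

# inverse of project_local: meters -> lon/lat about an origin
.local_to_lonlat <- function(xy, origin) {
  R <- 6371008.8
  deg <- 180 / pi
  cbind(lon = origin[1] + xy[, 1] / (R * cos(origin[2] * pi / 180)) * deg,
        lat = origin[2] + xy[, 2] / R * deg)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

#' Write a synthetic study to disk in pipeline formats
#'
#' Emits, per city, a road-segment GeoJSON (50 m grid-street segments
#' around the city centroid), a mobile-readings CSV with GPS positions
#' jittered around the segment midpoints, a feature-table CSV with sidecar
#' schema, and a true-surface CSV; plus a validation-sites CSV and a study
#' JSON with cities, parameters and seed. The written tree exercises the
#' same readers the real pipeline uses.
#'
#' @param study A `"synthetic_study"` from [make_study()].
#' @param dir Output directory (created if needed).
#' @param gps_jitter_m SD of the GPS jitter applied to reading positions.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, gps_jitter_m = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(study$seed + 55L)
  for (i in seq_len(nrow(study$cities))) {
    cid <- study$cities$city_id[i]
    origin <- c(study$cities$lon[i], study$cities$lat[i])
    ft <- study$features[[cid]]
    n <- nrow(ft)
    side <- ceiling(sqrt(n))
    gx <- ((seq_len(n) - 1L) %% side) * 100
    gy <- ((seq_len(n) - 1L) %/% side) * 100
    geom <- lapply(seq_len(n), function(k) {
      xy <- rbind(c(gx[k] - 25, gy[k]), c(gx[k] + 25, gy[k]))
      .local_to_lonlat(xy, origin)
    })
    segs <- structure(list(segment_id = ft$segment_id,
                           city_id = rep(cid, n), geometry = geom),
                      class = "road_segments")
    write_segments_geojson(segs, file.path(dir, paste0(cid, "_segments.geojson")))

    rd <- study$readings[[cid]]
    k <- match(rd$segment_id, ft$segment_id)
    mid <- .local_to_lonlat(cbind(gx[k] + stats::rnorm(nrow(rd), 0, gps_jitter_m),
                                  gy[k] + stats::rnorm(nrow(rd), 0, gps_jitter_m)),
                            origin)
    out_rd <- data.frame(reading_id = rd$reading_id,
                         time = format(as.POSIXct(rd$drive_day, tz = "UTC") +
                                         11 * 3600 + seq_len(nrow(rd)) %% 3600,
                                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                         lon = mid[, 1], lat = mid[, 2],
                         pollutant = rd$pollutant, value = rd$value)
    utils::write.csv(out_rd, file.path(dir, paste0(cid, "_readings.csv")),
                     row.names = FALSE)
    write_feature_table(ft, file.path(dir, paste0(cid, "_features.csv")))
    utils::write.csv(data.frame(segment_id = names(study$truth[[cid]]),
                                value = unname(study$truth[[cid]])),
                     file.path(dir, paste0(cid, "_truth.csv")), row.names = FALSE)
  }
  # validation sites at the matching target segment midpoints
  tgt <- study$cities[study$cities$role == "target", ]
  ft <- study$features[[tgt$city_id]]
  side <- ceiling(sqrt(nrow(ft)))
  k <- match(study$validation$segment_id, ft$segment_id)
  xy <- cbind(((k - 1L) %% side) * 100, ((k - 1L) %/% side) * 100)
  ll <- .local_to_lonlat(xy, c(tgt$lon, tgt$lat))
  utils::write.csv(data.frame(site_id = study$validation$site_id,
                              lon = ll[, 1], lat = ll[, 2],
                              value = study$validation$value),
                   file.path(dir, "validation_sites.csv"), row.names = FALSE)
  jsonlite::write_json(list(scenario = study$scenario, seed = study$seed,
                            cities = study$cities, params = study$params),
                       file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate a synthetic study and write it to disk
#'
#' @param scenario One of [SCENARIOS].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param n_segments,n_validation Study size.
#' @param params Generator parameters.
#' @return The study object, invisibly; files under `out_dir`.
#' @export
run_simulate <- function(scenario, seed, out_dir, n_segments = 400,
                         n_validation = 82, params = synthetic_defaults()) {
  study <- make_study(scenario, n_segments = n_segments,
                      n_validation = n_validation, seed = seed,
                      params = params)
  write_study(study, out_dir)
  invisible(study)
}

#' Run the preprocessing stage from a configuration
#'
#' Config fields: `readings` (CSV path), `segments` (GeoJSON path),
#' `pollutant`, optional `reference` (CSV with `hour,value`), `max_snap_m`,
#' `temporal` (`"additive"`/`"none"`), `out_aggregates`, `out_provenance`,
#' `seed`.
#'
#' @param config A YAML path or a named list.
#' @return The aggregates data.frame, invisibly; CSV + provenance JSON
#'   written to the configured paths.
#' @export
run_preprocess <- function(config) {
  cfg <- .read_config(config)
  readings <- read_mobile_readings(cfg$readings)
  segments <- read_segments_geojson(cfg$segments)
  reference <- if (!is.null(cfg$reference)) {
    rf <- utils::read.csv(cfg$reference, stringsAsFactors = FALSE)
    rf$hour <- as.POSIXct(rf$hour, tz = "UTC")
    rf
  }
  res <- preprocess_campaign(readings, segments, cfg$pollutant,
                             reference = reference,
                             max_snap_m = cfg$max_snap_m %||% 35,
                             temporal = cfg$temporal %||% "additive")
  write_aggregates(res$aggregates, cfg$out_aggregates)
  prov <- c(res$provenance,
            list(seed = cfg$seed %||% NA, config_hash = .config_hash(cfg)))
  jsonlite::write_json(prov, cfg$out_provenance %||%
                         paste0(cfg$out_aggregates, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res$aggregates)
}

#' Fit and evaluate a transfer (or local) LUR model from a configuration
#'
#' Mirrors the model taxonomy of the application: a single-source stepwise
#' model applied directly (`"slr"`), a single-source CORAL-aligned ridge
#' (`"coral"`), and their inverse-distance-weighted multi-source ensembles
#' (`"idw_slr"`, `"idw_coral"`). With `mode = "slr"` and the source equal to
#' the target this is the local reference model.
#'
#' Config fields: `features` (named list city -> feature CSV),
#' `aggregates` (named list source city -> aggregates CSV), `target`
#' (city id), `cities` (list of `city_id`, `lon`, `lat`), optional
#' `distances_km` (named), `validation` (CSV with `segment_id,value` or
#' site coordinates handled upstream), `lambda_reg`, `ridge_alpha`,
#' `idw_power`, SLR thresholds, `out_predictions`, `out_report`, `seed`.
#'
#' @param config A YAML path or a named list.
#' @param mode One of `"slr"`, `"coral"`, `"idw_slr"`, `"idw_coral"`.
#' @return List with `model`, `predictions` (data.frame) and `report`
#'   (`"lur_eval"` or `NULL`), invisibly; outputs written if configured.
#' @export
run_transfer <- function(config, mode = c("slr", "coral", "idw_slr", "idw_coral")) {
  mode <- match.arg(mode)
  cfg <- .read_config(config)
  sources <- names(cfg$aggregates)
  if (mode %in% c("idw_slr", "idw_coral") && length(sources) < 2)
    stop("mode ", mode, " requires >= 2 source cities, got ", length(sources))
  if (mode %in% c("slr", "coral") && length(sources) != 1)
    stop("mode ", mode, " requires exactly 1 source city, got ", length(sources))
  tables <- lapply(cfg$features, read_feature_table)
  check_feature_columns(tables)
  X_t <- tables[[cfg$target]]
  pred_cols <- setdiff(names(X_t), "segment_id")

  fit_one <- function(src, method) {
    agg <- utils::read.csv(cfg$aggregates[[src]], stringsAsFactors = FALSE,
                           colClasses = c(segment_id = "character"))
    ft <- tables[[src]]
    idx <- match(agg$segment_id, ft$segment_id)
    ok <- !is.na(idx)
    X_s <- ft[idx[ok], pred_cols, drop = FALSE]
    y_s <- agg$value[ok]
    if (method == "coral") {
      coral_lur(X_s, y_s, X_t[pred_cols],
                lambda_reg = cfg$lambda_reg,
                ridge_alpha = cfg$ridge_alpha %||% 1)
    } else {
      fit_slr(X_s, y_s, gain_min = cfg$gain_min %||% 0.01,
              p_drop = cfg$p_drop %||% 0.10, vif_max = cfg$vif_max %||% 3)
    }
  }

  base_method <- if (mode %in% c("coral", "idw_coral")) "coral" else "slr"
  members <- lapply(sources, fit_one, method = base_method)
  names(members) <- sources
  model <- if (mode %in% c("idw_slr", "idw_coral")) {
    locations <- if (!is.null(cfg$cities))
      do.call(rbind, lapply(cfg$cities, as.data.frame))
    idw_ensemble(members, locations = locations, target = cfg$target,
                 p = cfg$idw_power %||% 1,
                 distances_km = unlist(cfg$distances_km))
  } else members[[1]]

  pred <- predict(model, X_t)
  predictions <- data.frame(segment_id = X_t$segment_id, prediction = pred)
  report <- NULL
  if (!is.null(cfg$validation)) {
    val <- utils::read.csv(cfg$validation, stringsAsFactors = FALSE)
    if (!"segment_id" %in% names(val))
      stop("validation CSV must carry segment_id (match sites first with ",
           "match_validation_sites())")
    idx <- match(as.character(val$segment_id), predictions$segment_id)
    ok <- !is.na(idx)
    report <- evaluate(predictions$prediction[idx[ok]], val$value[ok])
  }
  if (!is.null(cfg$out_predictions))
    utils::write.csv(predictions, cfg$out_predictions, row.names = FALSE)
  if (!is.null(cfg$out_report) && !is.null(report)) {
    jsonlite::write_json(c(unclass(report)[c("n", "r2", "mae", "rmse",
                                             "pearson_r", "ccc")],
                           list(mode = mode, seed = cfg$seed %||% NA,
                                config_hash = .config_hash(cfg))),
                         cfg$out_report, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(model = model, predictions = predictions, report = report))
}
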