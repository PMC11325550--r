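# Config-driven pipeline runners: simulate -> preprocess -> transfer,
# exercising the on-disk exchange formats end to end.

write_small_study <- function(dir, scenario = "covariate_shift_only",
                              seed = 77, n_segments = 150) {
  run_simulate(scenario, seed = seed, out_dir = dir, n_segments = n_segments,
               n_validation = 40)
}

test_that("run_simulate writes a complete, reproducible study tree", {
  d1 <- file.path(tempdir(), "study1")
  d2 <- file.path(tempdir(), "study2")
  unlink(c(d1, d2), recursive = TRUE)
  write_small_study(d1)
  write_small_study(d2)
  expected <- c("TGT_segments.geojson", "TGT_readings.csv", "TGT_features.csv",
                "SRC_NEAR_features.csv", "SRC_FAR_features.csv",
                "validation_sites.csv", "study.json")
  expect_true(all(file.exists(file.path(d1, expected))))
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  expect_error(run_simulate("not_a_preset", 1, tempfile()), "arg")
})

test_that("run_preprocess reproduces the study aggregates from raw files", {
  d <- file.path(tempdir(), "study_pp")
  unlink(d, recursive = TRUE)
  study <- write_small_study(d)
  out_agg <- file.path(d, "agg.csv")
  cfg <- list(readings = file.path(d, "TGT_readings.csv"),
              segments = file.path(d, "TGT_segments.geojson"),
              pollutant = "NO2", temporal = "none",
              out_aggregates = out_agg, seed = 77)
  agg <- run_preprocess(cfg)
  expect_true(file.exists(out_agg))
  prov <- jsonlite::read_json(paste0(out_agg, ".provenance.json"))
  expect_equal(prov$seed, 77)
  expect_match(prov$config_hash, "^[a-f0-9]{32}$")
  # GPS jitter is small, grid spacing 100 m: snapping recovers the segment
  direct <- mean_of_means(study$readings$TGT)
  idx <- match(agg$segment_id, direct$segment_id)
  expect_gt(cor(agg$value, direct$value[idx]), 0.99)
  # winsorizing clamps only tails: medians agree closely
  expect_equal(median(agg$value), median(direct$value), tolerance = 0.05)

  cfg$readings <- file.path(d, "nope.csv")
  expect_error(run_preprocess(cfg), "not found")
})

test_that("a malformed readings row errors with its line number", {
  f <- file.path(tempdir(), "bad.csv")
  writeLines(c("reading_id,time,lon,lat,pollutant,value",
               "r1,2019-05-20T10:00:00Z,4.9,52.37,NO2,21.0",
               "r2,2019-05-20T10:00:01Z,4.9,52.37,NO2,oops"), f)
  expect_error(read_mobile_readings(f), "line 3")
})

test_that("the six-model taxonomy runs from one study directory", {
  d <- file.path(tempdir(), "study_tx")
  unlink(d, recursive = TRUE)
  study <- write_small_study(d, scenario = "both_shifts_tobler", seed = 78,
                             n_segments = 200)
  # per-source aggregates from the in-memory readings (already segment-keyed)
  for (src in c("SRC_NEAR", "SRC_FAR", "TGT"))
    write_aggregates(mean_of_means(study$readings[[src]]),
                     file.path(d, paste0(src, "_agg.csv")))
  val <- read.csv(file.path(d, "validation_sites.csv"))
  val$segment_id <- study$validation$segment_id
  write.csv(val, file.path(d, "validation.csv"), row.names = FALSE)

  base <- list(features = list(TGT = file.path(d, "TGT_features.csv"),
                               SRC_NEAR = file.path(d, "SRC_NEAR_features.csv"),
                               SRC_FAR = file.path(d, "SRC_FAR_features.csv")),
               target = "TGT",
               cities = lapply(seq_len(nrow(study$cities)), function(i)
                 as.list(study$cities[i, c("city_id", "lon", "lat")])),
               validation = file.path(d, "validation.csv"),
               seed = 78)
  reports <- list()
  for (src in c("SRC_NEAR", "SRC_FAR")) {
    for (mode in c("slr", "coral")) {
      cfg <- base
      cfg$aggregates <- setNames(list(file.path(d, paste0(src, "_agg.csv"))), src)
      r <- run_transfer(cfg, mode = mode)
      reports[[paste(src, mode)]] <- r$report
      expect_s3_class(r$report, "lur_eval")
      expect_equal(nrow(r$predictions), 200)
    }
  }
  cfg <- base
  cfg$aggregates <- list(SRC_NEAR = file.path(d, "SRC_NEAR_agg.csv"),
                         SRC_FAR = file.path(d, "SRC_FAR_agg.csv"))
  cfg$out_report <- file.path(d, "idw_coral.json")
  cfg$out_predictions <- file.path(d, "idw_coral_pred.csv")
  r_ic <- run_transfer(cfg, mode = "idw_coral")
  expect_true(file.exists(cfg$out_report))
  rep_json <- jsonlite::read_json(cfg$out_report)
  expect_equal(rep_json$mode, "idw_coral")
  expect_false(is.null(rep_json$ccc))
  expect_equal(rep_json$n, 40)
  cfg$out_report <- NULL
  r_is <- run_transfer(cfg, mode = "idw_slr")
  reports[["idw_coral"]] <- r_ic$report
  reports[["idw_slr"]] <- r_is$report
  expect_length(reports, 6)

  # ensemble weights concentrate on the near source per the IDW rule
  d_km <- city_distances_km(study$cities, "TGT", c("SRC_NEAR", "SRC_FAR"))
  expect_equal(unname(r_ic$model$weights), unname(idw_weights(d_km)))
  expect_gte(unname(r_ic$model$weights["SRC_NEAR"]), 0.9)

  # local reference: slr with source == target
  cfg_local <- base
  cfg_local$aggregates <- list(TGT = file.path(d, "TGT_agg.csv"))
  r_local <- run_transfer(cfg_local, mode = "slr")
  expect_s3_class(r_local$model, "slr_lur")
  expect_gt(r_local$report$r2, 0.2)

  # source-count preconditions
  expect_error(run_transfer(cfg_local, mode = "idw_coral"), ">= 2")
  expect_error(run_transfer(cfg, mode = "coral"), "exactly 1")
})

test_that("rerunning a transfer writes byte-identical outputs", {
  d <- file.path(tempdir(), "study_det")
  unlink(d, recursive = TRUE)
  study <- write_small_study(d, seed = 79, n_segments = 100)
  write_aggregates(mean_of_means(study$readings$SRC_NEAR),
                   file.path(d, "near_agg.csv"))
  cfg <- list(features = list(TGT = file.path(d, "TGT_features.csv"),
                              SRC_NEAR = file.path(d, "SRC_NEAR_features.csv")),
              aggregates = list(SRC_NEAR = file.path(d, "near_agg.csv")),
              target = "TGT", seed = 79,
              out_predictions = file.path(d, "pred.csv"))
  run_transfer(cfg, mode = "coral")
  h1 <- tools::md5sum(cfg$out_predictions)
  run_transfer(cfg, mode = "coral")
  expect_identical(unname(tools::md5sum(cfg$out_predictions)), unname(h1))
})
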