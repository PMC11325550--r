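# Model evaluation. Note the field convention adopted throughout: R^2 is the
# *squared Pearson correlation* between predictions and observations, not
# 1 - SSE/SST; under systematic bias the two differ, and long-term external
# validation in this literature reports the former. Lin's concordance
# correlation coefficient (CCC) complements it by penalizing both location
# and scale disagreement.

#' Evaluate predictions against observations
#'
#' Computes n, squared Pearson correlation (R^2), MAE, RMSE, Pearson r and
#' Lin's concordance correlation coefficient. CCC uses population (1/n)
#' moments: `2 r sx sy / (sx^2 + sy^2 + (mx - my)^2)`.
#'
#' @param pred,obs Numeric vectors of equal length (>= 3), finite.
#' @return An object of class `"lur_eval"`: list with `n`, `r2`, `mae`,
#'   `rmse`, `pearson_r`, `ccc` and `residuals` (pred - obs). If either
#'   vector has zero variance, correlation-based metrics are `NaN` with a
#'   warning; MAE/RMSE are still reported.
#' @export
evaluate <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("evaluate: length mismatch")
  if (length(pred) < 3) stop("evaluate: need >= 3 pairs")
  if (!all(is.finite(pred)) || !all(is.finite(obs)))
    stop("evaluate: non-finite values")
  res <- pred - obs
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  n <- length(pred)
  vx <- stats::var(pred); vy <- stats::var(obs)
  if (vx == 0 || vy == 0) {
    warning("zero variance: correlation-based metrics undefined")
    r <- NaN; ccc <- NaN
  } else {
    r <- stats::cor(pred, obs)
    sx2 <- vx * (n - 1) / n
    sy2 <- vy * (n - 1) / n
    ccc <- 2 * r * sqrt(sx2 * sy2) / (sx2 + sy2 + (mean(pred) - mean(obs))^2)
  }
  structure(list(n = n, r2 = r^2, mae = mae, rmse = rmse,
                 pearson_r = r, ccc = ccc, residuals = res),
            class = "lur_eval")
}

#' @export
print.lur_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d sites\n", x$n))
  cat(sprintf("  R2 (squared Pearson): %.3f\n", x$r2))
  cat(sprintf("  MAE: %.3f   RMSE: %.3f\n", x$mae, x$rmse))
  cat(sprintf("  Pearson r: %.3f   CCC: %.3f\n", x$pearson_r, x$ccc))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and, optionally, a one-row CSV with columns
#' `model,R2,MAE,RMSE` mirroring the usual validation-table layout.
#'
#' @param report A `"lur_eval"` object.
#' @param json_path Output JSON path, or `NULL` to skip.
#' @param csv_path Output CSV path, or `NULL` to skip.
#' @param model Model label written to the CSV row.
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL,
                              model = "model") {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report)[c("n", "r2", "mae", "rmse",
                                           "pearson_r", "ccc")],
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(data.frame(model = model, R2 = report$r2,
                                MAE = report$mae, RMSE = report$rmse),
                     csv_path, row.names = FALSE)
  invisible(report)
}

#' Match fixed validation sites to road segments
#'
#' Each site is paired with its nearest segment if within `max_match_m`
#' meters (perpendicular distance to the segment polyline); farther sites are
#' excluded. Ties go to the smallest `segment_id`.
#'
#' @param sites Data.frame with `site_id`, `lon`, `lat` (and typically a
#'   long-term `value`).
#' @param segments A `"road_segments"` object (WGS84 geometry), or projected
#'   geometry when `sites` carry `x`/`y` columns.
#' @param max_match_m Match threshold in meters (default 20).
#' @param origin Projection reference `c(lon, lat)`.
#' @return The matched sites with `segment_id` and `match_dist_m` columns.
#' @export
match_validation_sites <- function(sites, segments, max_match_m = 20,
                                   origin = NULL) {
  snap_to_segments(sites, segments, max_snap_m = max_match_m, origin = origin)
}
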