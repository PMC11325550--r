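# Inverse-distance-weighted fusion of per-source-city models. Instead of
# interpolating observations, the classic IDW scheme is applied to whole
# fitted models: each source city's model predicts every target segment, and
# the predictions are combined with weights proportional to the inverse
# source-to-target city distance. By Tobler's first law nearby cities share
# emission patterns, so conditional shift is damped by up-weighting the
# nearer sources. The same weights apply to all target segments
# (conditional shift differs between cities, not within the target), and the
# layer is model-agnostic: it wraps CORAL members (IDW_Coral) and stepwise
# members (IDW_SLR) identically.

#' Normalized inverse-distance weights
#'
#' `w_i = d_i^{-p} / sum_j d_j^{-p}`.
#'
#' @param distances_km Positive source-to-target distances.
#' @param p IDW power (default 1).
#' @return Weights summing to 1.
#' @export
idw_weights <- function(distances_km, p = 1) {
  if (!length(distances_km)) stop("idw_weights: need at least one source")
  if (any(distances_km <= 0))
    stop("idw_weights: zero or negative distance (source equals target; ",
         "transfer unnecessary)")
  w <- distances_km^(-p)
  w / sum(w)
}

#' Great-circle distances between city centroids
#'
#' @param locations Data.frame with `city_id`, `lon`, `lat` (WGS84 degrees).
#' @param target City id of the target.
#' @param sources City ids of the sources.
#' @return Named vector of distances in km.
#' @export
city_distances_km <- function(locations, target, sources) {
  idx <- match(c(target, sources), locations$city_id)
  if (anyNA(idx))
    stop("unknown city id(s): ",
         paste(c(target, sources)[is.na(idx)], collapse = ", "))
  t_xy <- c(locations$lon[idx[1]], locations$lat[idx[1]])
  d <- geosphere::distHaversine(t_xy,
                                cbind(locations$lon[idx[-1]],
                                      locations$lat[idx[-1]])) / 1000
  stats::setNames(d, sources)
}

#' Assemble an inverse-distance-weighted model ensemble
#'
#' @param members Named list of fitted per-source models (names are source
#'   city ids); each must support `predict(model, newdata)` on the target
#'   feature table.
#' @param locations Data.frame with `city_id`, `lon`, `lat`, or `NULL` when
#'   `distances_km` is supplied directly.
#' @param target Target city id.
#' @param p IDW power (default 1).
#' @param distances_km Optional named vector of straight-line distances (km)
#'   overriding the great-circle computation.
#' @return An object of class `"idw_ensemble"` with members, weights (sum to
#'   1, one per source) and distances.
#' @export
idw_ensemble <- function(members, locations = NULL, target = NULL, p = 1,
                         distances_km = NULL) {
  if (!length(members)) stop("idw_ensemble: no member models")
  if (is.null(names(members)) || any(names(members) == ""))
    stop("idw_ensemble: members must be named by source city id")
  if (is.null(distances_km)) {
    if (is.null(locations) || is.null(target))
      stop("idw_ensemble: provide locations + target, or distances_km")
    distances_km <- city_distances_km(locations, target, names(members))
  } else {
    miss <- setdiff(names(members), names(distances_km))
    if (length(miss))
      stop("idw_ensemble: no distance for source(s): ",
           paste(miss, collapse = ", "))
    distances_km <- distances_km[names(members)]
  }
  structure(list(members = members,
                 weights = idw_weights(distances_km, p = p),
                 distances_km = distances_km,
                 p = p,
                 target = target),
            class = "idw_ensemble")
}

#' Predict from an IDW model ensemble
#'
#' Per target segment, the weighted sum of member predictions; a convex
#' combination, so each ensemble prediction lies within the range of its
#' member predictions.
#'
#' @param object An `"idw_ensemble"`.
#' @param newdata Target feature table.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.idw_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(as.data.frame(newdata))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% object$weights)
}

#' @export
print.idw_ensemble <- function(x, ...) {
  cat(sprintf("Inverse-distance-weighted model ensemble (p = %g)\n", x$p))
  for (nm in names(x$members))
    cat(sprintf("  %s: distance %.0f km, weight %.4f\n",
                nm, x$distances_km[[nm]], x$weights[[nm]]))
  invisible(x)
}

#' Serialize an IDW ensemble description to JSON
#'
#' Member models are referenced by city id; serialize them separately with
#' [coral_to_json()] or [slr_to_json()].
#'
#' @param ensemble An `"idw_ensemble"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
idw_to_json <- function(ensemble, path) {
  jsonlite::write_json(list(sources = names(ensemble$members),
                            distances_km = as.list(ensemble$distances_km),
                            weights = as.list(ensemble$weights),
                            p = ensemble$p,
                            target = ensemble$target),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
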