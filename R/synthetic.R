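# Synthetic multi-city study generator. Emulates the statistical structure
# the transfer setting assumes: (1) covariate shift -- per-city feature
# distributions with different means/scales; (2) conditional shift with
# distance decay -- city-specific regression coefficients drawn from a
# spatial process with an exponential kernel over city centroids, so nearby
# cities share emission patterns; (3) drive-day sampling -- mobile campaigns
# that revisit random segment subsets on each day with day-level and 1-Hz
# observation noise. The true concentration response saturates at high
# covariate values, so models fitted in a low-range city and extrapolated
# into a high-range city overpredict -- the failure mode covariance
# alignment is designed to avoid.

#' Default generator parameters for the synthetic study
#'
#' Ten predictor columns with realistic LUR scales (vehicles/day, m^2, m,
#' persons), response coefficients giving an NO2-like surface (mean around
#' 28, SD around 4 ug/m^3), campaign sizes mirroring short source campaigns
#' (30 days, mean drive pass 1.8) and a longer target campaign, and shift
#' magnitudes for the scenario presets.
#'
#' @return Named list of generator parameters.
#' @export
synthetic_defaults <- function() {
  nm <- c("traffic_nearest", "traffic_major_100", "hd_traffic_nearest",
          "roadlength_100", "industry_500", "port_5000", "residential_300",
          "natural_1000", "urban_green_300", "population_1000")
  means <- stats::setNames(
    c(3500, 8000, 300, 400, 30000, 2e6, 150000, 4e5, 50000, 8000), nm)
  sds <- stats::setNames(
    c(750, 2000, 120, 150, 20000, 1.5e6, 60000, 3e5, 40000, 4000), nm)
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  traffic <- c("traffic_nearest", "traffic_major_100", "hd_traffic_nearest",
               "roadlength_100")
  R[traffic, traffic] <- 0.5
  diag(R) <- 1
  R["population_1000", "residential_300"] <- R["residential_300", "population_1000"] <- 0.5
  R["natural_1000", "urban_green_300"] <- R["urban_green_300", "natural_1000"] <- 0.3
  beta <- stats::setNames(
    c(2e-3, 5e-4, 4e-3, 4e-3, 3e-5, 1e-6, 8e-6, -4e-6, -1e-5, 2.5e-4), nm)
  list(feature_names = nm,
       feature_means = means,
       feature_sds = sds,
       feature_cor = R,
       beta_general = beta,
       intercept = 10,
       knee_sd = 0.5,       # saturation knee at base mean + 0.5 SD
       slope_frac = 0.1,    # response slope beyond the knee
       sigma_segment = 2,   # unexplained segment-level SD (ug/m3)
       tau_rel = 1.0,       # city-effect SD relative to |beta_general|
       ell_km = 200,        # length scale of the city-effect kernel
       shift_sd = 5.3,      # covariate shift magnitude in source SDs
       shift_dir = stats::setNames(c(1, 1, 1, 1, 1, 1, 1, -1, -1, 1), nm),
       sd_scale = 1.3,      # covariate shift: target SD scale factor
       n_days_source = 30, pass_source = 1.8,
       n_days_target = 40, pass_target = 1.7,
       sigma_day = 3, sigma_obs = 8, points_per_visit = 5)
}

#' Simulate a per-city feature table
#'
#' Multivariate-normal rows rectified at 0 (areas, lengths, intensities and
#' population cannot be negative). Covariate shift between cities is
#' realized by passing different means/covariances.
#'
#' @param n_segments Number of road segments (rows).
#' @param mean_vector Named feature means.
#' @param covariance SPD covariance matrix matching `mean_vector`.
#' @param seed Integer seed.
#' @param city_id Prefix for generated segment ids.
#' @return A `feature_table` data.frame with `segment_id`.
#' @export
make_city_features <- function(n_segments, mean_vector, covariance, seed = 1,
                               city_id = "city") {
  d <- length(mean_vector)
  if (!all(dim(covariance) == c(d, d)))
    stop("make_city_features: dimension mismatch between mean and covariance")
  set.seed(seed)
  X <- MASS::mvrnorm(n_segments, mu = mean_vector, Sigma = covariance)
  X <- pmax(X, 0)
  colnames(X) <- names(mean_vector)
  ft <- data.frame(segment_id = sprintf("%s-%05d", city_id, seq_len(n_segments)),
                   X, stringsAsFactors = FALSE, check.names = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# Per-column saturating response transform: identity below the knee, slope
# `slope_frac` above it.
.saturate <- function(X, knee, slope_frac) {
  for (j in colnames(X)) {
    k <- knee[[j]]
    hi <- X[, j] > k
    X[hi, j] <- k + slope_frac * (X[hi, j] - k)
  }
  X
}

#' Draw city-specific coefficient perturbations from a spatial process
#'
#' For each predictor j, the per-city effects are a zero-mean Gaussian
#' vector with covariance `tau_j^2 * exp(-D / ell_km)` over great-circle
#' city distances D: nearby cities get correlated emission-pattern
#' deviations, distant cities nearly independent ones.
#'
#' City effects model *pattern* differences (which streets are polluted, not
#' how polluted the city is overall): when `profile` is supplied, each
#' city's effect vector is projected orthogonal to it, so the effect
#' redistributes the response across predictors without moving the citywide
#' mean level at the reference covariate profile. Level differences belong
#' to the shared component of the conditional law.
#'
#' @param locations Data.frame with `city_id`, `lon`, `lat`.
#' @param tau Named vector of per-predictor effect SDs.
#' @param ell_km Kernel length scale in km.
#' @param seed Integer seed.
#' @param profile Optional reference covariate profile (named vector, e.g.
#'   mean saturated features) to project out.
#' @return Matrix (cities x predictors) of coefficient perturbations.
#' @export
draw_city_effects <- function(locations, tau, ell_km, seed = 1,
                              profile = NULL) {
  n <- nrow(locations)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      D[i, j] <- geosphere::distHaversine(
        c(locations$lon[i], locations$lat[i]),
        c(locations$lon[j], locations$lat[j])) / 1000
  }
  K <- exp(-D / ell_km)
  L <- chol(K + diag(1e-10, n))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * length(tau)), n, length(tau))
  B <- crossprod(L, Z) %*% diag(tau, length(tau))
  dimnames(B) <- list(locations$city_id, names(tau))
  if (!is.null(profile)) {
    m <- profile[colnames(B)]
    m <- m / sqrt(sum(m^2))
    B <- B - (B %*% m) %*% t(m)
  }
  B
}

#' Simulate the true long-term concentration surface of one city
#'
#' `Y = intercept + s(X) (beta_general + beta_city) + eps`, where `s` is the
#' per-column saturating transform and `eps` is segment-level N(0,
#' sigma_segment^2) variation. `beta_city = 0` gives a shared conditional
#' distribution across cities.
#'
#' @param features Feature table of the city.
#' @param beta_general Named coefficient vector shared by all cities.
#' @param beta_city Named per-city coefficient perturbation (default 0).
#' @param intercept Baseline concentration.
#' @param knee Named vector of saturation knees (covariate units).
#' @param slope_frac Response slope beyond the knee.
#' @param sigma_segment SD of unexplained segment-level variation.
#' @param seed Integer seed.
#' @return Named numeric vector of true values, one per segment.
#' @export
make_true_surface <- function(features, beta_general, beta_city = 0,
                              intercept = 10, knee, slope_frac = 0.2,
                              sigma_segment = 2, seed = 1) {
  X <- as.matrix(features[setdiff(names(features), "segment_id")])
  if (!all(names(beta_general) %in% colnames(X)))
    stop("make_true_surface: beta/feature column mismatch")
  X <- X[, names(beta_general), drop = FALSE]
  S <- .saturate(X, knee, slope_frac)
  b <- beta_general
  if (!identical(beta_city, 0)) b <- b + beta_city[names(beta_general)]
  set.seed(seed)
  y <- intercept + drop(S %*% b) + stats::rnorm(nrow(X), 0, sigma_segment)
  stats::setNames(y, features$segment_id)
}

#' Visit probability giving a requested mean drive pass
#'
#' Campaigns only observe segments driven at least once, so the requested
#' mean drive pass is matched in conditional expectation:
#' solves `n q / (1 - (1-q)^n) = target` for the daily visit probability q.
#'
#' @param mean_pass Requested mean number of distinct drive days per
#'   measured segment (> 1).
#' @param n_days Number of campaign days.
#' @return Daily visit probability in (0, 1].
#' @export
calibrate_visit_rate <- function(mean_pass, n_days) {
  if (mean_pass <= 1 || mean_pass > n_days)
    stop("calibrate_visit_rate: mean_pass must be in (1, n_days]")
  f <- function(q) n_days * q / (1 - (1 - q)^n_days) - mean_pass
  stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
}

#' Simulate a mobile monitoring campaign over a known true surface
#'
#' Each day an independent random subset of segments is driven; every
#' visited segment yields `points_per_visit` 1-Hz readings
#' `Y + day_effect + obs_noise`, with a campaign-wide day effect
#' N(0, sigma_day^2) shared by all segments of that day (meteorology) and
#' independent N(0, sigma_obs^2) instrument noise per reading.
#'
#' @param Y Named true surface (names are segment ids).
#' @param n_days Number of campaign days.
#' @param mean_pass Requested mean drive pass over measured segments; the
#'   daily visit probability is calibrated with [calibrate_visit_rate()].
#' @param sigma_day Day-effect SD.
#' @param sigma_obs Per-reading noise SD.
#' @param points_per_visit Readings recorded per segment visit.
#' @param seed Integer seed.
#' @param start_date First campaign day.
#' @param pollutant Pollutant label carried on the readings.
#' @return Data.frame of readings: `reading_id`, `segment_id`, `drive_day`,
#'   `pollutant`, `value`.
#' @export
sample_mobile_campaign <- function(Y, n_days, mean_pass = 1.8, sigma_day = 3,
                                   sigma_obs = 8, points_per_visit = 5,
                                   seed = 1, start_date = as.Date("2019-05-20"),
                                   pollutant = "NO2") {
  if (n_days < 1) stop("sample_mobile_campaign: n_days must be >= 1")
  q <- if (mean_pass <= 1) 1 / n_days else calibrate_visit_rate(mean_pass, n_days)
  set.seed(seed)
  n_seg <- length(Y)
  out <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    visited <- which(stats::runif(n_seg) < q)
    if (!length(visited)) next
    day_eff <- stats::rnorm(1, 0, sigma_day)
    m <- length(visited) * points_per_visit
    vals <- rep(Y[visited], each = points_per_visit) + day_eff +
      stats::rnorm(m, 0, sigma_obs)
    out[[day]] <- data.frame(
      segment_id = rep(names(Y)[visited], each = points_per_visit),
      drive_day = start_date + day - 1L,
      pollutant = pollutant,
      value = vals,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(segment_id = character(), drive_day = as.Date(character()),
                      pollutant = character(), value = numeric())
  res$reading_id <- sprintf("r%07d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[c("reading_id", "segment_id", "drive_day", "pollutant", "value")]
}

#' Scenario presets of the synthetic study
#' @export
SCENARIOS <- c("no_shift", "covariate_shift_only", "conditional_shift_only",
               "both_shifts_tobler")

#' Assemble a complete synthetic multi-city study
#'
#' Three cities mimic the application geometry: a target with two source
#' cities at roughly 57 and 620 km straight-line distance. Depending on the
#' scenario, the target feature distribution is shifted/rescaled (covariate
#' shift) and per-city coefficient perturbations with distance-decaying
#' correlation are drawn (conditional shift):
#' \describe{
#'   \item{no_shift}{identical feature distribution and identical
#'     conditional law in all cities.}
#'   \item{covariate_shift_only}{target feature means shifted by
#'     `shift_sd` source SDs in the direction `shift_dir` (urban
#'     densification: traffic, industry, port, residential and population
#'     up; natural and green space down) and SDs scaled by `sd_scale`;
#'     shared coefficients.}
#'   \item{conditional_shift_only}{identical features; spatially correlated
#'     city coefficients (`tau_rel`, `ell_km`).}
#'   \item{both_shifts_tobler}{both mechanisms together.}
#' }
#'
#' @param scenario One of [SCENARIOS].
#' @param n_segments Segments per city.
#' @param n_validation Validation sites sampled from target segments.
#' @param seed Integer master seed; all sub-draws derive from it.
#' @param params Generator parameters ([synthetic_defaults()]).
#' @return An object of class `"synthetic_study"`: city table, per-city
#'   feature tables, true surfaces, mobile readings, validation sites and
#'   the generator parameters.
#' @export
make_study <- function(scenario = SCENARIOS, n_segments = 2000,
                       n_validation = 82, seed = 1,
                       params = synthetic_defaults()) {
  scenario <- match.arg(scenario)
  p <- params
  cities <- data.frame(
    city_id = c("TGT", "SRC_NEAR", "SRC_FAR"),
    lon = c(4.90, 4.47, 12.57),
    lat = c(52.37, 51.92, 55.68),
    role = c("target", "source", "source"),
    stringsAsFactors = FALSE)

  base_cov <- diag(p$feature_sds) %*% p$feature_cor %*% diag(p$feature_sds)
  dimnames(base_cov) <- list(p$feature_names, p$feature_names)
  knee <- p$feature_means + p$knee_sd * p$feature_sds

  shift_target <- scenario %in% c("covariate_shift_only", "both_shifts_tobler")
  tgt_means <- if (shift_target)
    p$feature_means + p$shift_sd * p$shift_dir * p$feature_sds
  else p$feature_means
  tgt_cov <- if (shift_target) base_cov * p$sd_scale^2 else base_cov

  conditional <- scenario %in% c("conditional_shift_only", "both_shifts_tobler")
  beta_city <- if (conditional) {
    draw_city_effects(cities, tau = p$tau_rel * abs(p$beta_general),
                      ell_km = p$ell_km, seed = seed + 11L,
                      profile = p$feature_means)
  } else {
    matrix(0, nrow(cities), length(p$beta_general),
           dimnames = list(cities$city_id, names(p$beta_general)))
  }

  features <- list(); truth <- list(); readings <- list()
  for (i in seq_len(nrow(cities))) {
    cid <- cities$city_id[i]
    is_target <- cities$role[i] == "target"
    mu <- if (is_target) tgt_means else p$feature_means
    Sg <- if (is_target) tgt_cov else base_cov
    ft <- make_city_features(n_segments, mu, Sg, seed = seed + 100L * i,
                             city_id = cid)
    yy <- make_true_surface(ft, p$beta_general, beta_city[cid, ],
                            intercept = p$intercept, knee = knee,
                            slope_frac = p$slope_frac,
                            sigma_segment = p$sigma_segment,
                            seed = seed + 100L * i + 1L)
    n_days <- if (is_target) p$n_days_target else p$n_days_source
    pass <- if (is_target) p$pass_target else p$pass_source
    rd <- sample_mobile_campaign(yy, n_days, mean_pass = pass,
                                 sigma_day = p$sigma_day,
                                 sigma_obs = p$sigma_obs,
                                 points_per_visit = p$points_per_visit,
                                 seed = seed + 100L * i + 2L)
    features[[cid]] <- ft; truth[[cid]] <- yy; readings[[cid]] <- rd
  }

  set.seed(seed + 7L)
  vidx <- sample(n_segments, min(n_validation, n_segments))
  validation <- data.frame(
    site_id = sprintf("site-%03d", seq_along(vidx)),
    segment_id = features$TGT$segment_id[vidx],
    value = unname(truth$TGT[vidx]),
    stringsAsFactors = FALSE)

  structure(list(scenario = scenario, cities = cities, features = features,
                 truth = truth, readings = readings, validation = validation,
                 beta_city = beta_city, params = p, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study '%s' (seed %d)\n", x$scenario, x$seed))
  cat(sprintf("  %d cities, %d segments each, %d validation sites\n",
              nrow(x$cities), nrow(x$features[[1]]), nrow(x$validation)))
  invisible(x)
}

#' Per-segment aggregates of a study campaign
#'
#' Convenience wrapper: mean-of-means aggregation of the simulated readings
#' of one city, joined with that city's feature rows.
#'
#' @param study A `"synthetic_study"`.
#' @param city_id City id.
#' @return List with `X` (feature rows), `y` (aggregate values) and the
#'   aggregate table `agg`.
#' @export
study_aggregates <- function(study, city_id) {
  agg <- mean_of_means(study$readings[[city_id]])
  ft <- study$features[[city_id]]
  idx <- match(agg$segment_id, ft$segment_id)
  list(X = ft[idx, setdiff(names(ft), "segment_id"), drop = FALSE],
       y = agg$value, agg = agg)
}
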