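# Small in-code fixtures shared across the test files.

# readings data.frame with sensible defaults
toy_readings <- function(values, pollutant = "NO2",
                         times = NULL, lon = 4.9, lat = 52.37,
                         drive_day = NULL) {
  n <- length(values)
  if (is.null(times))
    times <- as.POSIXct("2019-05-20 10:00:00", tz = "UTC") + seq_len(n) * 60
  df <- data.frame(reading_id = sprintf("r%03d", seq_len(n)),
                   time = times,
                   lon = rep_len(lon, n), lat = rep_len(lat, n),
                   pollutant = rep_len(pollutant, n), value = values,
                   stringsAsFactors = FALSE)
  df$drive_day <- if (is.null(drive_day)) as.Date(df$time, tz = "UTC")
                  else rep_len(drive_day, n)
  df
}

# road_segments object from a named list of two-column coordinate matrices
toy_segments <- function(geoms, city_id = "X") {
  structure(list(segment_id = names(geoms),
                 city_id = rep(city_id, length(geoms)),
                 geometry = unname(geoms)),
            class = "road_segments")
}

# random symmetric positive-definite matrix
random_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(d * d), d)
  crossprod(M) + diag(0.5, d)
}

# rectangle ring (closed) as a coordinate matrix
rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
}

# quick feature/response pair with a known linear signal
toy_xy <- function(n = 200, seed = 1, sd_noise = 0.1) {
  set.seed(seed)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * X$x1 + rnorm(n, sd = sd_noise)
  list(X = X, y = y)
}
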