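# Mobile-data preprocessing: range filters, winsorizing, temporal
# correction, snapping, mean-of-means aggregation.

test_that("range filter drops out-of-range values with inclusive bounds", {
  no2 <- toy_readings(c(-1, 10, 600))
  expect_equal(filter_range(no2, "NO2")$value, 10)
  edge <- toy_readings(c(0, 500))
  expect_equal(filter_range(edge, "NO2")$value, c(0, 500))
  ufp <- toy_readings(c(100, 250, 499999, 600000), pollutant = "UFP")
  expect_equal(filter_range(ufp, "UFP")$value, c(250, 499999))
  expect_error(filter_range(no2, "PM25"), "unknown pollutant")
})

test_that("range filter preserves order and is idempotent", {
  r <- toy_readings(c(30, -5, 12, 700, 1))
  f1 <- filter_range(r, "NO2")
  expect_equal(f1$value, c(30, 12, 1))
  expect_equal(filter_range(f1, "NO2"), f1)
})

test_that("winsorizing clamps at interpolated 2.5/97.5 percentiles", {
  expect_equal(winsorize(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  w <- winsorize(1:1000)
  # linear interpolation between order statistics: 1 + p*(n-1)
  expect_equal(min(w), 25.975)
  expect_equal(max(w), 975.025)
  expect_length(w, 1000)
  set.seed(42)
  x <- rlnorm(500)
  q <- quantile(x, c(0.025, 0.975), names = FALSE)
  wx <- winsorize(x)
  expect_true(all(wx >= q[1] & wx <= q[2]))
  expect_error(winsorize(numeric(0)), "empty")
})

test_that("temporal correction is additive against the campaign mean", {
  r <- toy_readings(c(30, 20, 25))
  hours <- as.POSIXct(trunc(r$time, "hours"), tz = "UTC")
  ref_const <- data.frame(hour = unique(hours), value = 7)
  expect_equal(temporal_correct(r, ref_const)$value, r$value)

  # one hour sits 5 above the reference mean
  h <- unique(hours)
  stopifnot(length(h) == 1)
  ref <- data.frame(hour = c(h, h + 3600, h + 7200), value = c(10, 5, 0))
  expect_equal(temporal_correct(r, ref)$value[1], 30 - (10 - 5))
})

test_that("corrections cancel over a uniform campaign (brute-force toy)", {
  # 3 days x 4 hours, every hour measured once: deviations sum to zero
  hrs <- as.POSIXct("2019-05-20 09:00:00", tz = "UTC") + 3600 * (0:11)
  set.seed(1)
  ref <- data.frame(hour = hrs, value = rnorm(12, 20, 4))
  r <- toy_readings(rnorm(12, 30, 2), times = hrs + 600)
  corrected <- temporal_correct(r, ref)
  expect_equal(mean(corrected$value), mean(r$value))
})

test_that("temporal correction errors name missing hours; UFP passes through", {
  r <- toy_readings(c(30), times = as.POSIXct("2019-05-20 13:30:00", tz = "UTC"))
  ref <- data.frame(hour = as.POSIXct("2019-05-20 09:00:00", tz = "UTC"),
                    value = 5)
  expect_error(temporal_correct(r, ref), "2019-05-20 13:00")
  u <- toy_readings(c(9000), pollutant = "UFP")
  expect_equal(temporal_correct(u, ref)$value, 9000)
})

test_that("snapping assigns nearest segment, ties to smallest id", {
  # two parallel east-west streets 20 m apart, in projected coordinates
  segs <- toy_segments(list(B = rbind(c(0, 20), c(50, 20)),
                            A = rbind(c(0, 0), c(50, 0))))
  pts <- data.frame(x = c(25, 25, 25), y = c(0, 10, 200))
  out <- snap_to_segments(pts, segs, max_snap_m = 35)
  expect_equal(nrow(out), 2)             # 200 m point dropped
  expect_equal(out$segment_id, c("A", "A"))  # on-segment; equidistant tie -> A
  expect_equal(out$snap_dist_m, c(0, 10))
  expect_error(snap_to_segments(pts, toy_segments(setNames(list(), character()))),
               "empty segment set")
})

test_that("snapping works on lon/lat input via the local projection", {
  origin <- c(4.9, 52.37)
  seg_ll <- toy_segments(list(S1 = cbind(
    c(4.9, 4.901), c(52.37, 52.37))))
  r <- toy_readings(c(1), lon = 4.9005, lat = 52.37)
  out <- snap_to_segments(r, seg_ll, max_snap_m = 35, origin = origin)
  expect_equal(out$segment_id, "S1")
  expect_lt(out$snap_dist_m, 1)
})

test_that("mean of means averages daily means, unweighted", {
  r <- data.frame(segment_id = "s1",
                  drive_day = as.Date(c("2019-05-20", "2019-05-20", "2019-05-21")),
                  value = c(10, 20, 30), pollutant = "NO2")
  agg <- mean_of_means(r)
  expect_equal(agg$value, 22.5)
  expect_equal(agg$n_drive_pass, 2L)
  expect_equal(agg$n_points, 3L)
})

test_that("mean of means equals the plain mean with one reading per day", {
  set.seed(3)
  r <- data.frame(segment_id = "s1",
                  drive_day = as.Date("2019-05-20") + 0:9,
                  value = rnorm(10, 25, 3))
  expect_equal(mean_of_means(r)$value, mean(r$value))
})

test_that("mean of means is invariant to within-day duplication", {
  set.seed(4)
  r <- data.frame(segment_id = sample(c("a", "b"), 40, TRUE),
                  drive_day = as.Date("2019-05-20") + sample(0:4, 40, TRUE),
                  value = rnorm(40, 20, 5))
  dup <- rbind(r, r)
  expect_equal(mean_of_means(dup)$value, mean_of_means(r)$value)
})

test_that("aggregates lie within the range of their daily means", {
  set.seed(5)
  r <- data.frame(segment_id = sample(letters[1:6], 300, TRUE),
                  drive_day = as.Date("2019-05-20") + sample(0:19, 300, TRUE),
                  value = rnorm(300, 20, 5))
  agg <- mean_of_means(r)
  daily <- aggregate(value ~ segment_id + drive_day, r, mean)
  for (i in seq_len(nrow(agg))) {
    d <- daily$value[daily$segment_id == agg$segment_id[i]]
    expect_gte(agg$value[i], min(d))
    expect_lte(agg$value[i], max(d))
    expect_gte(agg$n_points[i], agg$n_drive_pass[i])
  }
})

test_that("dropping a drive day only changes segments visited that day", {
  set.seed(6)
  r <- data.frame(segment_id = sample(letters[1:8], 200, TRUE),
                  drive_day = as.Date("2019-05-20") + sample(0:9, 200, TRUE),
                  value = rnorm(200, 20, 5))
  day0 <- as.Date("2019-05-20")
  full <- mean_of_means(r)
  less <- mean_of_means(r[r$drive_day != day0, ])
  visited <- unique(r$segment_id[r$drive_day == day0])
  for (s in setdiff(full$segment_id, visited)) {
    expect_equal(less$value[less$segment_id == s],
                 full$value[full$segment_id == s])
  }
})

test_that("preprocess_campaign chains the stages and reports provenance", {
  segs <- toy_segments(list(S = rbind(c(4.9, 52.37), c(4.901, 52.37))))
  r <- toy_readings(c(10, 20, 700, 30), lon = 4.9004, lat = 52.37)
  r$drive_day <- as.Date("2019-05-20") + c(0, 0, 0, 1)
  res <- preprocess_campaign(r, segs, "NO2", temporal = "none")
  expect_equal(res$provenance$removed_range_filter, 1)
  w <- winsorize(c(10, 20, 30))   # campaign-wide winsorizing precedes snapping
  expect_equal(res$aggregates$value, mean(c(mean(w[1:2]), w[3])))
  expect_equal(res$aggregates$n_drive_pass, 2L)
})
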