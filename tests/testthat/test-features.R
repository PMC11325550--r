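# Buffer-based GIS feature extraction.

test_that("buffer area: full containment gives the disk area", {
  mids <- rbind(c(0, 0))
  lu <- list(rings = list(rect_ring(-1000, -1000, 1000, 1000)),
             class = "industry")
  out <- buffer_area_features(mids, lu, classes = "industry", buffers_m = 100)
  expect_equal(unname(out[1, "industry_100"]), pi * 100^2, tolerance = 1e-9)
})

test_that("buffer area: absent classes give zero columns and unknown classes error", {
  mids <- rbind(c(0, 0))
  lu <- list(rings = list(rect_ring(-10, -10, 10, 10)), class = "industry")
  out <- buffer_area_features(mids, lu, buffers_m = c(100, 300))
  expect_true(all(out[, c("port_100", "port_300", "water_100")] == 0))
  bad <- list(rings = lu$rings, class = "parking_lot")
  expect_error(buffer_area_features(mids, bad), "unknown land-use class")
})

test_that("buffer area: half-plane polygon through the centroid gives half the disk", {
  # verified against a Monte-Carlo point-in-polygon oracle
  mids <- rbind(c(0, 0))
  half <- rect_ring(0, -5000, 5000, 5000)   # x >= 0 half within range
  lu <- list(rings = list(half), class = "natural")
  out <- buffer_area_features(mids, lu, classes = "natural", buffers_m = 300)
  expect_equal(unname(out[1, "natural_300"]), pi * 300^2 / 2, tolerance = 1e-9)
  set.seed(1)
  p <- matrix(runif(2 * 20000, -300, 300), ncol = 2)
  inside <- rowSums(p^2) <= 300^2 & p[, 1] >= 0
  mc <- mean(inside) * 600^2
  expect_equal(unname(out[1, "natural_300"]), mc, tolerance = 0.02)
})

test_that("buffer areas are monotone in radius and translation invariant", {
  set.seed(7)
  mids <- rbind(c(12, -40))
  lu <- list(rings = list(rect_ring(-150, -300, 90, 55),
                          rect_ring(-400, 0, 400, 120)),
             class = c("industry", "industry"))
  r <- c(100, 300, 500, 1000)
  out <- buffer_area_features(mids, lu, classes = "industry", buffers_m = r)
  expect_true(all(diff(as.numeric(out)) >= 0))
  shift <- c(12345, -6789)
  lu2 <- list(rings = lapply(lu$rings, function(g) sweep(g, 2, -shift)),
              class = lu$class)
  out2 <- buffer_area_features(mids + rep(shift, each = 1), lu2,
                               classes = "industry", buffers_m = r)
  expect_equal(out2, out, tolerance = 1e-9)
})

test_that("traffic: nearest-road intensities and chord road length", {
  mids <- rbind(c(0, 0))
  roads <- list(lines = list(rbind(c(-500, 0), c(500, 0))),
                intensity = 5000, hd_intensity = 400, major = TRUE)
  out <- traffic_features(mids, roads, buffers_m = 100)
  expect_equal(unname(out[1, "traffic_nearest"]), 5000)
  expect_equal(unname(out[1, "hd_traffic_nearest"]), 400)
  expect_equal(unname(out[1, "traffic_nearest_major"]), 5000)
  # 1000 m straight road crossing the 100 m buffer through its center
  expect_equal(unname(out[1, "roadlength_100"]), 200, tolerance = 1e-9)
  expect_equal(unname(out[1, "traffic_100"]), 5000 * 200, tolerance = 1e-6)
})

test_that("traffic: empty buffers give zeros; no major roads warns", {
  mids <- rbind(c(0, 0))
  roads <- list(lines = list(rbind(c(5000, 5000), c(6000, 5000))),
                intensity = 3000, hd_intensity = 100, major = FALSE)
  expect_warning(out <- traffic_features(mids, roads, buffers_m = c(25, 100)),
                 "no major roads")
  expect_equal(unname(out[1, "roadlength_25"]), 0)
  expect_equal(unname(out[1, "traffic_100"]), 0)
  expect_equal(unname(out[1, "traffic_nearest_major"]), 0)
  expect_equal(unname(out[1, "traffic_nearest"]), 3000)  # nearest road has no cutoff
})

test_that("population: uniform density integrates to d * pi * r^2", {
  mids <- rbind(c(0, 0))
  # 10x10 grid of 200 m cells, 40 persons each -> 0.001 persons/m2
  cells <- list(); cnt <- numeric(0)
  for (i in 0:9) for (j in 0:9) {
    cells <- c(cells, list(rect_ring(-1000 + i * 200, -1000 + j * 200,
                                     -800 + i * 200, -800 + j * 200)))
    cnt <- c(cnt, 40)
  }
  pop <- list(rings = cells, count = cnt)
  out <- population_features(mids, pop, buffers_m = c(300, 500))
  expect_equal(unname(out[1, "population_300"]), 0.001 * pi * 300^2, tolerance = 1e-6)
  expect_equal(unname(out[1, "population_500"]), 0.001 * pi * 500^2, tolerance = 1e-6)
  none <- population_features(mids, list(rings = cells, count = rep(0, 100)),
                              buffers_m = 300)
  expect_equal(unname(none[1, "population_300"]), 0)
})

test_that("population: buffer straddling two cells is area-weighted", {
  mids <- rbind(c(0, 0))
  pop <- list(rings = list(rect_ring(-200, -200, 0, 200),
                           rect_ring(0, -200, 200, 200)),
              count = c(80, 160))
  out <- population_features(mids, pop, buffers_m = 100)
  # half the disk in each cell; cell areas 200x400
  frac <- (pi * 100^2 / 2) / (200 * 400)
  expect_equal(unname(out[1, "population_100"]), frac * 80 + frac * 160,
               tolerance = 1e-9)
})

make_toy_city <- function(origin, seed) {
  set.seed(seed)
  n <- 4
  xs <- seq(0, 300, length.out = n)
  geom <- lapply(xs, function(x) {
    xy <- rbind(c(x - 25, 0), c(x + 25, 0))
    transferlur:::.local_to_lonlat(xy, origin)
  })
  segs <- toy_segments(setNames(geom, sprintf("g%02d", seq_len(n))))
  ring_ll <- function(m) transferlur:::.local_to_lonlat(m, origin)
  layers <- list(
    landuse = list(rings = list(ring_ll(rect_ring(-100, -100, 150, 100))),
                   class = "residential"),
    roads = list(lines = list(ring_ll(rbind(c(-500, 10), c(500, 10)))),
                 intensity = 4000, hd_intensity = 250, major = TRUE),
    population = list(rings = list(ring_ll(rect_ring(-200, -200, 200, 200))),
                      count = 500))
  list(segments = segs, layers = layers)
}

test_that("feature tables share columns across cities and round-trip losslessly", {
  a <- make_toy_city(c(4.9, 52.37), 1)
  b <- make_toy_city(c(12.57, 55.68), 2)
  fta <- build_feature_table(a$segments, a$layers,
                             landuse_buffers = c(100, 300),
                             traffic_buffers = c(25, 100))
  ftb <- build_feature_table(b$segments, b$layers,
                             landuse_buffers = c(100, 300),
                             traffic_buffers = c(25, 100))
  expect_identical(names(fta), names(ftb))
  expect_true(check_feature_columns(list(A = fta, B = ftb)))
  expect_error(check_feature_columns(list(A = fta, B = ftb[, -5])),
               "differ")
  expect_false(any(is.na(as.matrix(fta[-1]))))

  path <- file.path(tempdir(), "ft.csv")
  write_feature_table(fta, path)
  back <- read_feature_table(path)
  expect_identical(back$segment_id, fta$segment_id)
  for (nm in setdiff(names(fta), "segment_id"))
    expect_identical(back[[nm]], fta[[nm]])
})
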