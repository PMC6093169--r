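test_that("off-axis angles follow the viewing geometry of each mode", {
  expect_equal(off_axis_angle_scanning(c(3, 4), c(3, 4), 10), 0)
  expect_equal(off_axis_angle_scanning(c(13, 4), c(3, 4), 10), 45)
  r <- seq(0, 50, by = 5)
  a <- off_axis_angle_scanning(cbind(r, 0), c(0, 0), 20)
  expect_true(all(diff(a) > 0)) # strictly increasing in r
  # fixed mode: zero at the station centre, equals scanning on the axis
  expect_equal(off_axis_angle_fixed(c(7, 9), c(7, 9), 15, c(10, 10)), 0)
  px <- cbind(runif(20, 0, 32), runif(20, 0, 32))
  expect_equal(off_axis_angle_fixed(px, c(16, 16), 24, c(16, 16)),
               off_axis_angle_scanning(px, c(16, 16), 24), tolerance = 1e-12)
  # pixels mirrored through the station axis plane subtend equal angles
  ctr <- c(16, 16); st <- c(26, 16)
  expect_equal(off_axis_angle_fixed(c(22, 11), st, 24, ctr),
               off_axis_angle_fixed(c(22, 21), st, 24, ctr), tolerance = 1e-12)
})

test_that("acceptance weight halves at half the acceptance angle", {
  expect_equal(acceptance_weight(0, 2.6), 1)
  expect_equal(acceptance_weight(1.3, 2.6), exp(-2.77 / 4))
  expect_equal(acceptance_weight(1.3, 2.6), 0.5003, tolerance = 1e-4)
  # FWHM property holds for any rho
  for (rho in c(0.25, 1, 2.6, 15))
    expect_equal(acceptance_weight(rho / 2, rho), 0.5003, tolerance = 1e-4)
})

test_that("station colors match an untruncated double-loop oracle", {
  set.seed(7)
  plane <- matrix(runif(32 * 32, 0, 255), 32, 32)
  # geometry chosen so the default 2*rho truncation covers the whole image
  # from every station: worst-case off-axis angle is atan(sqrt(2)*32/40)
  # = 48.5 deg in scanning mode (and < 2*29.5 deg in fixed mode), < 2*30
  geom <- scene_geometry(2 * atan(16 / 40) * 180 / pi, 32)
  expect_equal(geom$d, 40, tolerance = 1e-12)
  centers <- cbind(x = c(16, 6.5, 25), y = c(16, 9, 28.5))
  for (mode in c("scanning", "fixed")) {
    grid <- structure(list(
      stations = data.frame(id = 1:3, x = centers[, 1], y = centers[, 2],
                            ring = 0L, rho = 30, n_pixels = 1L),
      assignment = tessellate_stations(centers[, 1], centers[, 2], 32, 32),
      mode = mode, geom = geom), class = "sampling_grid")
    got <- station_colors(grid, plane) # default truncation
    ora <- vapply(1:3, function(s)
      oracle_station_color(plane, centers[s, 1], centers[s, 2], 30, 40, mode),
      numeric(1))
    expect_equal(got, ora, tolerance = 1e-9)
    # explicit untruncated evaluation agrees too
    expect_equal(station_colors(grid, plane, trunc = Inf), ora,
                 tolerance = 1e-9)
  }
})

test_that("truncation at 2 rho changes station colors by at most ~1e-5", {
  set.seed(8)
  plane <- matrix(runif(48 * 48, 0, 255), 48, 48)
  geom <- scene_geometry(60, 48)
  g <- build_scanning_grid(geom, eye_params(12, 12, 6), c(48, 48))
  v2 <- station_colors(g, plane, trunc = 2)
  vInf <- station_colors(g, plane, trunc = Inf)
  expect_lt(max(abs(v2 - vInf)), 255 * 5e-5)
})

test_that("a uniform image yields the input value at every station", {
  plane <- matrix(93.7, 40, 56)
  geom <- scene_geometry(50, 40)
  for (g in list(build_scanning_grid(geom, eye_params(6, 5, 4), c(56, 40)),
                 build_fixed_grid(geom, eye_params(6, 5, 4), c(56, 40)))) {
    v <- station_colors(g, plane)
    ok <- !is.na(v)
    # weighted mean of a constant is the constant: also checks that the
    # implemented weights are normalised to 1 per station
    expect_equal(v[ok], rep(93.7, sum(ok)), tolerance = 1e-9)
  }
})

test_that("station values are convex combinations of pixel values", {
  set.seed(9)
  plane <- matrix(sample(c(0, 63, 191, 255), 30 * 30, TRUE), 30, 30)
  geom <- scene_geometry(45, 30)
  g <- build_scanning_grid(geom, eye_params(10, 10, 7), c(30, 30))
  v <- station_colors(g, plane)
  expect_true(all(v >= min(plane) - 1e-12 & v <= max(plane) + 1e-12))
})

test_that("increasing the acceptance angle cannot sharpen a step edge", {
  plane <- step_edge(40, 32)
  geom <- scene_geometry(45, 32)
  dev_for_rho <- function(rho) {
    g <- build_scanning_grid(geom, eye_params(8, 8, rho), c(40, 32))
    abs(station_colors(g, plane) - 127.5)
  }
  d_small <- dev_for_rho(3)
  d_big <- dev_for_rho(9) # same phi: identical station set
  expect_true(all(d_big <= d_small + 1e-9))
})

test_that("a station with no pixels in reach is reported by id", {
  # station far outside the image whose truncated support misses every pixel
  geom <- scene_geometry(2 * atan(16 / 40) * 180 / pi, 32)
  centers <- cbind(x = c(16, 120), y = c(16, 140))
  grid <- structure(list(
    stations = data.frame(id = 1:2, x = centers[, 1], y = centers[, 2],
                          ring = 0L, rho = 0.5, n_pixels = c(1024L, 0L)),
    assignment = tessellate_stations(centers[, 1], centers[, 2], 32, 32),
    mode = "scanning", geom = geom), class = "sampling_grid")
  # every pixel is ~74 deg off-axis for station 2: all weights underflow
  plane <- matrix(100, 32, 32)
  expect_error(station_colors(grid, plane, stations = 2L), "station\\(s\\) 2 ")
  expect_equal(station_colors(grid, plane, stations = 1L)[1], 100,
               tolerance = 1e-12)
})
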