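test_that("scanning grid covers the image and partitions its pixels", {
  # spacing 10 px in both axes on a 100 x 100 image
  geom <- scene_geometry(60, 100)
  phi <- 2 * atan(5 / geom$d) * 180 / pi # spacing exactly 10
  g <- build_scanning_grid(geom, eye_params(phi, phi, 2), c(100, 100))
  expect_gte(nrow(g$stations), 100)
  expect_true(all(g$assignment >= 1 & g$assignment <= nrow(g$stations)))
  expect_equal(sum(g$stations$n_pixels), 100 * 100)
  expect_equal(unname(g$spacing), c(10, 10), tolerance = 1e-12)
  # scanning stations all carry the ring-0 acceptance angle
  expect_true(all(g$stations$rho == 2))
  expect_true(all(g$stations$ring == 0L))
  # translation invariance: all fully interior cells are congruent, so the
  # pixel counts of interior stations are identical
  st <- g$stations
  interior <- st$x > 15 & st$x < 85 & st$y > 15 & st$y < 85
  expect_true(sum(interior) > 20)
  expect_equal(length(unique(st$n_pixels[interior])), 1L)
})

test_that("an image smaller than one cell yields a single-station grid", {
  geom <- scene_geometry(10, 16)
  g <- build_scanning_grid(geom, eye_params(60, 60, 5), c(16, 16))
  expect_equal(nrow(g$stations), 1L)
  expect_true(all(g$assignment == 1L))
})

test_that("sub-pixel spacing warns but still yields a valid partition", {
  geom <- scene_geometry(120, 48)
  expect_warning(
    g <- build_scanning_grid(geom, eye_params(0.9, 0.9, 2.6), c(32, 48)),
    "below one pixel")
  expect_equal(sum(g$stations$n_pixels), 32 * 48)
})

test_that("pixel assignment is the nearest-centre partition with id ties", {
  set.seed(41)
  for (rep in 1:3) {
    n <- 12
    sx <- runif(n, 0, 24); sy <- runif(n, 0, 18)
    got <- tessellate_stations(sx, sy, 24, 18)
    expect_identical(got, oracle_nn_assign(sx, sy, 24, 18))
  }
  # exact tie on the perpendicular bisector goes to the lowest id
  got <- tessellate_stations(c(4, 12), c(5, 5), 16, 10)
  expect_true(all(got[, 1:8] == 1L))
  expect_true(all(got[, 9:16] == 2L)) # pixel centres at x = 8.5 onwards
  tie <- tessellate_stations(c(4.5, 12.5), c(5, 5), 16, 10)
  expect_true(all(tie[, 9] == 1L)) # x = 8.5 is equidistant: lower id wins
  expect_error(tessellate_stations(c(1, 1), c(2, 2), 8, 8), "duplicate")
})

test_that("two-station tessellation boundary is the perpendicular bisector", {
  sx <- c(5.25, 17.75); sy <- c(3.5, 14.5)
  a <- tessellate_stations(sx, sy, 24, 20)
  for (j in 1:24) for (i in 1:20) {
    d1 <- (j - 0.5 - sx[1])^2 + (i - 0.5 - sy[1])^2
    d2 <- (j - 0.5 - sx[2])^2 + (i - 0.5 - sy[2])^2
    expect_identical(a[i, j], if (d1 <= d2) 1L else 2L)
  }
})

test_that("fixed grid has the 1 + 3R(R+1) concentric ring structure", {
  geom <- scene_geometry(60, 64)
  p <- eye_params(2, 2, 2)
  g <- build_fixed_grid(geom, p, c(64, 64), max_rings = 5)
  counts <- table(g$stations$ring)
  expect_equal(unname(counts[as.character(1:5)]), 6 * (1:5),
               ignore_attr = TRUE)
  for (R in 1:5)
    expect_equal(sum(g$stations$ring <= R), 1 + 3 * R * (R + 1))
  expect_equal(sum(g$stations$n_pixels), 64 * 64)
  # per-ring acceptance angles follow the quadratic rho model
  p2 <- eye_params(2, 2, c(2, 0.1, 0.01))
  g2 <- build_fixed_grid(geom, p2, c(64, 64), max_rings = 3)
  r3 <- g2$stations$rho[g2$stations$ring == 3]
  expect_equal(unique(r3), 2 + 3 * 0.1 + 9 * 0.01)
})

test_that("fixed-grid ellipse radii follow d tan(cumulative angle)", {
  # constant 1-degree horizontal angle, d = 100: ring 10 radius 100 tan(10)
  h <- 64
  alpha <- 2 * atan(h / 200) * 180 / pi # gives d = 100 exactly
  geom <- scene_geometry(alpha, h)
  expect_equal(geom$d, 100, tolerance = 1e-12)
  g <- build_fixed_grid(geom, eye_params(1, 1, 2), c(64, h), max_rings = 10)
  st <- g$stations[g$stations$ring == 10, ]
  rh <- max(st$x) - 32 # station at 3 o'clock
  expect_equal(rh, 17.633, tolerance = 1e-3)
  expect_equal(rh, 100 * tan(10 * pi / 180), tolerance = 1e-9)
  # equal angles and no eccentricity growth: rings are circles
  r <- sqrt((st$x - 32)^2 + (st$y - h / 2)^2)
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
})

test_that("near the centre, fixed-grid spacing matches the scanning grid", {
  # tan linearisation: for n*phi < 2 degrees the ring gap approaches the
  # scanning row spacing 2 d tan(phi/2) within 1%
  h <- 512
  geom <- scene_geometry(40, h)
  phi <- 0.5
  g <- build_fixed_grid(geom, eye_params(phi, phi, 2), c(512, h),
                        max_rings = 4)
  scan_sp <- hexagon_spacings(geom, eye_params(phi, phi, 2))[["vertical"]]
  top <- vapply(0:4, function(n) {
    min(g$stations$y[g$stations$ring == n])
  }, numeric(1))
  gaps <- -diff(top)
  expect_true(all(abs(gaps - scan_sp) / scan_sp < 0.01))
})

test_that("the grid truncates with a warning when angles accumulate to 90", {
  geom <- scene_geometry(179, 32) # d tiny: image never enclosed
  expect_warning(
    g <- build_fixed_grid(geom, eye_params(30, 30, 10), c(32, 32)),
    "90 degrees")
  expect_equal(g$n_rings, 2L) # rings 1 and 2 reach 60 deg; ring 3 would hit 90
  expect_equal(sum(g$stations$n_pixels), 32 * 32)
})

test_that("cell polygons agree with the brute-force nearest-centre rule", {
  geom <- scene_geometry(90, 64)
  p <- eye_params(14, 11, 8)
  g <- build_fixed_grid(geom, p, c(64, 64))
  cells <- station_cells(g)
  expect_length(cells, nrow(g$stations))
  checked <- 0
  for (j in seq(2, 64, by = 3)) {
    for (i in seq(2, 64, by = 3)) {
      p0 <- c(j - 0.5, i - 0.5)
      hits <- which(vapply(cells, function(v) inside_convex(p0, v, 1e-6),
                           logical(1)))
      if (length(hits) == 1L) { # skip points on (or numerically at) an edge
        expect_identical(g$assignment[i, j], hits)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 300)
})

test_that("one station owns the whole rectangle; cells export as text", {
  g <- build_scanning_grid(scene_geometry(10, 16), eye_params(60, 60, 5),
                           c(16, 16))
  cells <- station_cells(g)
  expect_equal(nrow(cells[[1]]), 4L)
  expect_equal(sort(cells[[1]][, 1]), c(0, 0, 16, 16))
  f <- tempfile(fileext = ".txt")
  export_cells(g, f)
  expect_equal(length(readLines(f)), 1L)
})
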