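test_that("uniform input renders to an identical uniform mosaic", {
  for (mode in c("scanning", "fixed")) {
    eye <- eye_model(eye_params(5, 4, 3), mode = mode)
    img <- uniform_field(50, 40, value = 87, channels = 3)
    m <- eye_view(img, eye, alpha_v = 35)
    expect_true(all(m$image == 87))
    expect_equal(dim(m$image), dim(img))
  }
})

test_that("a one-station grid renders the global weighted mean everywhere", {
  set.seed(21)
  plane <- matrix(runif(16 * 16, 0, 255), 16, 16)
  geom <- scene_geometry(10, 16)
  p <- eye_params(60, 60, 5)
  g <- build_scanning_grid(geom, p, c(16, 16))
  expect_equal(nrow(g$stations), 1L)
  m <- eye_view(plane, eye_model(p), alpha_v = 10)
  ora <- oracle_station_color(plane, 8, 8, 5, geom$d, "scanning")
  expect_true(all(m$image == floor(ora + 0.5)))
})

test_that("rendered pixels match nearest-centre station colors exactly", {
  set.seed(22)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  eye <- eye_model(eye_params(11, 9, 7))
  m <- eye_view(img, eye, alpha_v = 50)
  g <- m$grids[[1]]
  ora <- oracle_nn_assign(g$stations$x, g$stations$y, 64, 64)
  for (c in 1:3) {
    want <- matrix(floor(pmin(pmax(m$station_values[[c]][ora], 0), 255) + 0.5),
                   64, 64)
    expect_equal(m$image[, , c], want)
  }
})

test_that("re-rendering a solid mosaic reproduces it exactly", {
  # any mosaic whose cells all carry one color is a fixed point of the
  # pipeline: the convex Gaussian average of a constant is that constant
  img <- checkerboard(16, 16, cell = 4)
  eye <- eye_model(eye_params(60, 60, 5)) # one station: solid output
  m1 <- eye_view(img, eye, alpha_v = 10)
  expect_equal(length(unique(as.vector(m1$image))), 1L)
  m2 <- eye_view(m1$image, eye, alpha_v = 10)
  expect_identical(m2$image, m1$image)
  # and with many stations on a uniform mosaic
  eye2 <- eye_model(eye_params(10, 8, 5))
  u <- eye_view(uniform_field(48, 32, 201), eye2, alpha_v = 40)
  expect_identical(eye_view(u$image, eye2, alpha_v = 40)$image, u$image)
})

test_that("out-of-gamut recombined values are clipped to [0, 255]", {
  set.seed(23)
  gray <- matrix(runif(24 * 24, 50, 205), 24, 24)
  eye <- eye_model(eye_params(8, 8, 6))
  hot <- eye_view_files(list(gray), matrix(c(3, 1, -2), 1, 3), eye, 40)
  expect_true(all(hot$image >= 0 & hot$image <= 255))
  expect_true(any(hot$image == 255) && any(hot$image == 0)) # clipping engaged
  expect_true(all(hot$image == floor(hot$image)))           # 8-bit values
})

test_that("PNG, BMP and TIFF round-trip bit-identically", {
  img <- test_card(33, 21) # odd width exercises BMP row padding
  img[] <- floor(img + 0.5)
  for (ext in c("png", "bmp", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(img, f)
    back <- read_image(f)
    expect_identical(back$format, if (ext == "tiff") "tiff" else ext)
    expect_equal(back$data, img, tolerance = 1e-12)
  }
})

test_that("gray images round-trip as single-channel rasters", {
  g <- matrix(floor(seq(0, 255, length.out = 18 * 12) + 0.5), 18, 12)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(g, f)
    back <- read_image(f)
    expect_equal(dim(back$data), c(18, 12, 1))
    expect_equal(back$data[, , 1], g, tolerance = 1e-12)
  }
  # BMP is stored as 24-bit: gray content survives, replicated
  f <- tempfile(fileext = ".bmp")
  write_image(g, f)
  back <- read_image(f)
  expect_equal(back$data[, , 2], g, tolerance = 1e-12)
})

test_that("JPEG output writes with a lossy note and reads back", {
  img <- uniform_field(20, 16, 128, channels = 3)
  f <- tempfile(fileext = ".jpg")
  expect_message(write_image(img, f), "lossy")
  back <- read_image(f)
  expect_identical(back$format, "jpg")
  expect_equal(dim(back$data), c(16, 20, 3))
})

test_that("alpha-channel and indexed-color inputs are rejected", {
  f <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(8, 8, 4)), f)
  expect_error(read_image(f), "alpha channel")
  f2 <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(8, 8, 2)), f2) # gray + alpha
  expect_error(read_image(f2), "alpha channel")
  # minimal 8-bit indexed BMP (palette-based): header declares bpp = 8
  f3 <- tempfile(fileext = ".bmp")
  hdr <- as.raw(c(0x42, 0x4D, rep(0, 8), 54, 0, 0, 0,
                  40, rep(0, 3), 1, rep(0, 3), 1, rep(0, 3), 1, 0, 8, 0,
                  rep(0, 24)))
  writeBin(c(hdr, as.raw(0)), f3)
  expect_error(read_image(f3), "indexed-color")
  expect_error(read_image(tempfile(fileext = ".gif")), "not found")
  f4 <- tempfile(fileext = ".gif"); file.create(f4)
  expect_error(read_image(f4), "unsupported image format")
})
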