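#' Simulate the retinal sampling-station image of a photograph
#'
#' The main pipeline: superposes the eye's sampling grid on the photograph
#' (one grid per output channel when the eye model has per-channel spatial
#' parameters), computes every station's color as the Gaussian
#' acceptance-angle weighted average of the pixels it views, and renders the
#' mosaic by filling each station's cell with its color.
#'
#' @param image An image path, an `eye_image` from [read_image()], or a
#'   numeric array/matrix on the 0--255 scale (height x width x channels).
#' @param eye An [eye_model()] (an [eye_params()] is accepted and treated as
#'   a shared-parameter scanning/fixed model via `mode`).
#' @param alpha_v Vertical angle subtended by the image, degrees.
#' @param mode Used only when `eye` is a bare [eye_params()]:
#'   `"scanning"` or `"fixed"`.
#' @param trunc Truncation radius of the Gaussian sum, in units of the
#'   acceptance angle (see [station_colors()]).
#' @param verbose Emit grid-size messages.
#' @return An object of class `eye_mosaic`: `image` (8-bit array, same pixel
#'   dimensions as the input), `grids` (per-channel `sampling_grid`s),
#'   `station_values` (per-channel station colors before rounding), `eye`,
#'   `geom` and `input_format`.
#' @export
#' @examples
#' img <- checkerboard(64, 48, cell = 8)
#' bee <- eye_model(eye_params(1.6, 0.9, 2.6))
#' m <- eye_view(img, bee, alpha_v = 20)
eye_view <- function(image, eye, alpha_v, mode = c("scanning", "fixed"),
                     trunc = 2, verbose = FALSE) {
  if (inherits(eye, "eye_params")) eye <- eye_model(eye, match.arg(mode))
  stopifnot(inherits(eye, "eye_model"))
  img <- load_image_data(image)
  a <- img$data
  h <- dim(a)[1]; w <- dim(a)[2]; nc_in <- dim(a)[3]
  geom <- scene_geometry(alpha_v, h)
  nc_out <- if (eye$shared) nc_in else 3L
  grids <- build_channel_grids(eye, geom, c(w, h))
  if (verbose)
    message(sprintf("grid(s): %s stations; truncation at %g rho",
                    paste(vapply(grids, function(g) nrow(g$stations),
                                 integer(1)), collapse = "/"), trunc))
  vals <- vector("list", nc_out)
  for (c in seq_len(nc_out)) {
    g <- grids[[min(c, length(grids))]]
    plane <- a[, , min(c, nc_in)]
    vals[[c]] <- station_colors(g, plane, trunc = trunc)
  }
  out <- if (eye$shared)
    render_mosaic(grids[[1]], do.call(cbind, vals))
  else
    render_mosaic(rep(grids, length.out = 3)[1:3], vals)
  structure(list(image = out, grids = grids, station_values = vals,
                 eye = eye, geom = geom, input_format = img$format),
            class = "eye_mosaic")
}

#' Simulate from gray-scale filter photographs and a weighting matrix
#'
#' Recombination pipeline for chromatic treatment: up to nine gray-scale
#' photographs of the same scene, each taken through a different filter, are
#' sampled on the eye's grid(s) and combined into output channels through
#' the weighting matrix, channel `c` of station `n` being
#' `sum_f w[f, c] * C_nf`. With per-channel spatial parameters each output
#' channel is sampled on its own grid and the channel planes are merged per
#' pixel at render time.
#'
#' @param files A list (length 1--9) of image paths, `eye_image`s, or
#'   gray-scale matrices/arrays (0--255). Nominally gray RGB files must have
#'   channels equal within 1 level.
#' @param w A [weight_matrix()] (or path) with one row per file.
#' @inheritParams eye_view
#' @return An `eye_mosaic` with a 3-channel image.
#' @export
eye_view_files <- function(files, w, eye, alpha_v,
                           mode = c("scanning", "fixed"),
                           trunc = 2, verbose = FALSE) {
  if (inherits(eye, "eye_params")) eye <- eye_model(eye, match.arg(mode))
  stopifnot(inherits(eye, "eye_model"))
  w <- weight_matrix(w)
  if (!is.list(files)) files <- as.list(files)
  if (length(files) != nrow(w))
    stop(sprintf("%d input files but W has %d rows", length(files), nrow(w)))
  planes <- lapply(seq_along(files), function(f)
    as_gray_plane(load_image_data(files[[f]])$data, what = paste("file", f)))
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all input photographs must have the same pixel dimensions")
  h <- dims[1, 1]; wpx <- dims[2, 1]
  geom <- scene_geometry(alpha_v, h)
  grids <- build_channel_grids(eye, geom, c(wpx, h))
  vals <- vector("list", 3L)
  for (c in 1:3) {
    g <- grids[[min(c, length(grids))]]
    cf <- vapply(planes, function(p) station_colors(g, p, trunc = trunc),
                 numeric(nrow(g$stations)))
    vals[[c]] <- as.vector(combine_channels(cf, w)[, c])
  }
  fmt <- if (is.character(files[[1]])) image_format(files[[1]]) else NULL
  out <- render_mosaic(rep(grids, length.out = 3)[1:3], vals)
  structure(list(image = out, grids = grids, station_values = vals,
                 eye = eye, geom = geom, input_format = fmt),
            class = "eye_mosaic")
}

build_channel_grids <- function(eye, geom, image_size) {
  builder <- if (eye$mode == "scanning") build_scanning_grid else
    build_fixed_grid
  lapply(eye$channels, function(p) builder(geom, p, image_size))
}

load_image_data <- function(image) {
  if (is.character(image)) return(read_image(image))
  if (inherits(image, "eye_image")) return(image)
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (!(is.array(image) && length(dim(image)) == 3L))
    stop("`image` must be a path, an eye_image, or a 0-255 array/matrix")
  if (min(image) < 0 || max(image) > 255)
    stop("image arrays must be on the 0-255 scale")
  list(data = image, format = NULL)
}
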