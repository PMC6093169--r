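# rendering: fill each station's cell with its station color

# round half away from zero (values are non-negative after clipping)
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Render station colors into a mosaic raster
#'
#' Fills every pixel of the output raster with the color of the station that
#' owns it (the station whose cell contains the pixel centre). When each
#' output channel has its own grid, the channel planes are rendered
#' independently and stacked. Values are clipped to \[0, 255\] and rounded
#' half away from zero once, here.
#'
#' @param grids A single `sampling_grid` or a list of three (R, G, B).
#' @param colors A numeric matrix of station values (stations x channels)
#'   for a single grid, or a list of three per-grid station-value vectors.
#' @return Numeric array (height x width x channels) of 8-bit values.
#' @export
render_mosaic <- function(grids, colors) {
  if (inherits(grids, "sampling_grid")) {
    stopifnot(is.matrix(colors) || is.numeric(colors))
    colors <- cbind(colors)
    h <- nrow(grids$assignment); w <- ncol(grids$assignment)
    out <- array(NA_real_, c(h, w, ncol(colors)))
    for (c in seq_len(ncol(colors)))
      out[, , c] <- matrix(colors[grids$assignment, c], h, w)
  } else {
    stopifnot(is.list(grids), length(grids) == length(colors))
    h <- nrow(grids[[1]]$assignment); w <- ncol(grids[[1]]$assignment)
    out <- array(NA_real_, c(h, w, length(grids)))
    for (c in seq_along(grids))
      out[, , c] <- matrix(colors[[c]][grids[[c]]$assignment], h, w)
  }
  if (anyNA(out)) stop("a rendered pixel has no station color")
  round_half_up(clip255(out))
}

#' @export
print.eye_mosaic <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("eye mosaic: %d x %d px, %d channel(s), %s mode\n",
              d[2], d[1], d[3], x$eye$mode))
  ns <- vapply(x$grids, function(g) nrow(g$stations), integer(1))
  cat(sprintf("  stations per channel grid: %s\n", paste(ns, collapse = ", ")))
  invisible(x)
}

#' Display a mosaic or image array
#'
#' @param x An `eye_mosaic`.
#' @param ... Passed to [graphics::rasterImage()].
#' @export
plot.eye_mosaic <- function(x, ...) {
  a <- x$image / 255
  if (dim(a)[3] == 1L) a <- a[, , 1]
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(0:1, 0:1, asp = dim(a)[1] / dim(a)[2])
  graphics::rasterImage(grDevices::as.raster(a), 0, 0, 1, 1, ...)
  invisible(x)
}
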