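#' Off-axis angle in scanning mode
#'
#' In scanning mode the eye looks perpendicularly at each station's cell, so
#' the off-axis angle of a pixel is `atan(r / d)` with `r` the in-plane
#' Euclidean distance between the pixel and the station centre.
#'
#' @param pixel,station_center Length-2 numeric `(x, y)` in pixel
#'   coordinates (or two-column matrices for several pixels).
#' @param d Viewing distance in pixels (positive).
#' @return Off-axis angle(s) in degrees.
#' @export
off_axis_angle_scanning <- function(pixel, station_center, d) {
  if (any(d <= 0)) stop("`d` must be positive")
  pixel <- rbind(pixel); station_center <- rbind(station_center)
  r <- sqrt((pixel[, 1] - station_center[, 1])^2 +
            (pixel[, 2] - station_center[, 2])^2)
  unname(rad2deg(atan(r / d)))
}

#' Off-axis angle in fixed-viewpoint mode
#'
#' With the eye held at a fixed position at distance `d` on the normal
#' through the image centre, the off-axis angle of a pixel for a station is
#' the angle between the eye-to-station and eye-to-pixel vectors.
#'
#' @inheritParams off_axis_angle_scanning
#' @param image_center Length-2 numeric `(x, y)`: the point of the image
#'   plane on the eye's optical axis.
#' @return Off-axis angle(s) in degrees.
#' @export
off_axis_angle_fixed <- function(pixel, station_center, d, image_center) {
  if (any(d <= 0)) stop("`d` must be positive")
  pixel <- rbind(pixel); station_center <- rbind(station_center)
  ax <- station_center[, 1] - image_center[1]
  ay <- station_center[, 2] - image_center[2]
  bx <- pixel[, 1] - image_center[1]
  by <- pixel[, 2] - image_center[2]
  cosang <- (ax * bx + ay * by + d^2) /
    (sqrt(ax^2 + ay^2 + d^2) * sqrt(bx^2 + by^2 + d^2))
  unname(rad2deg(acos(pmin(1, pmax(-1, cosang)))))
}

#' Gaussian acceptance-angle weight
#'
#' Relative sensitivity of a sampling station to light arriving `alpha`
#' degrees off its optical axis: `exp(-2.77 (alpha / rho)^2)`, a Gaussian
#' whose full width at half maximum is the acceptance angle `rho` (the
#' constant 2.77 approximates 4 ln 2). A pixel half an acceptance angle
#' off axis therefore carries almost exactly half the on-axis weight.
#'
#' @param alpha Off-axis angle(s), degrees.
#' @param rho Acceptance angle, degrees (positive).
#' @return Weight(s) in (0, 1].
#' @export
#' @examples
#' acceptance_weight(1.3, 2.6) # ~0.5
acceptance_weight <- function(alpha, rho) {
  if (any(rho <= 0)) stop("`rho` must be positive")
  exp(-2.77 * (alpha / rho)^2)
}

#' Station colors of one image plane
#'
#' Computes, for every station of a grid, the Gaussian-weighted average of
#' pixel values: `sum(chi_i w_i) / sum(w_i)` with
#' `w_i = exp(-2.77 (alpha_i / rho)^2)`, where `alpha_i` is the off-axis
#' angle of pixel `i` in the grid's mode. For performance the sum is
#' truncated at `alpha_i > trunc * rho`, where the relative weight has
#' fallen to `exp(-2.77 trunc^2)` (about 1.5e-5 at the default `trunc = 2`);
#' set `trunc = Inf` to sum over every pixel of the image. A station whose
#' truncated support contains no pixel centre is evaluated untruncated, so
#' truncation never changes which stations are computable; an error naming
#' the station is raised only when every pixel weight underflows to zero
#' (a station aimed far outside the image with a tiny acceptance angle).
#'
#' @param grid A `sampling_grid`.
#' @param plane Numeric matrix (height x width) of pixel values on the
#'   0--255 scale (one color channel).
#' @param trunc Truncation radius in units of `rho`; `Inf` disables
#'   truncation.
#' @param stations Optional integer vector of station ids to evaluate
#'   (default: all stations owning at least one pixel).
#' @return Numeric vector of averaged values, indexed like
#'   `grid$stations$id`; stations that were not evaluated are `NA`.
#' @export
station_colors <- function(grid, plane, trunc = 2, stations = NULL) {
  stopifnot(inherits(grid, "sampling_grid"), is.matrix(plane))
  if (nrow(plane) != nrow(grid$assignment) ||
      ncol(plane) != ncol(grid$assignment))
    stop("`plane` does not match the grid's image size")
  st <- grid$stations
  if (is.null(stations)) stations <- st$id[st$n_pixels > 0L]
  w <- ncol(plane); h <- nrow(plane)
  tm <- if (is.finite(trunc)) trunc else -1
  vals <- cpp_gauss_sample(plane,
                           st$x[stations], st$y[stations],
                           st$rho[stations], grid$geom$d,
                           grid$mode == "fixed", w / 2, h / 2, tm)
  if (anyNA(c(vals)) || any(is.nan(vals))) {
    bad <- stations[is.nan(vals) | is.na(vals)]
    stop(sprintf("station(s) %s have no pixels with non-zero weight",
                 paste(bad, collapse = ", ")))
  }
  out <- rep(NA_real_, nrow(st))
  out[stations] <- vals
  out
}
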