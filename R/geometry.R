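#' Viewing distance implied by a subtended angle
#'
#' An observer for whom an image of height `h` pixels subtends a vertical
#' angle `alpha_v` is effectively watching the photograph from a distance
#' `d = h / (2 tan(alpha_v / 2))`, expressed in pixel units. All subsequent
#' angular geometry is computed from this distance.
#'
#' @param alpha_v Vertical angle subtended by the image, in degrees
#'   (strictly between 0 and 180).
#' @param h Image height in pixels (at least 1).
#' @return Viewing distance in pixel units.
#' @seealso [subtended_angle()] for the inverse relation.
#' @export
#' @examples
#' viewing_distance(90, 1000) # 500
viewing_distance <- function(alpha_v, h) {
  if (!is.numeric(alpha_v) || any(alpha_v <= 0) || any(alpha_v >= 180))
    stop("`alpha_v` must lie strictly between 0 and 180 degrees")
  if (!is.numeric(h) || any(h < 1))
    stop("`h` must be at least 1 pixel")
  h / (2 * tan(deg2rad(alpha_v) / 2))
}

#' Angle subtended by an extent seen from a distance
#'
#' Inverse of the geometry behind [viewing_distance()]: an object of size
#' `extent` watched frontally from `distance` (same physical units) subtends
#' `2 atan(extent / (2 distance))` degrees.
#'
#' @param distance Viewing distance (positive).
#' @param extent Linear extent of the viewed object (positive, same units).
#' @return Subtended angle in degrees.
#' @export
#' @examples
#' subtended_angle(1, 2) # 90
subtended_angle <- function(distance, extent) {
  if (!is.numeric(distance) || any(distance <= 0))
    stop("`distance` must be positive")
  if (!is.numeric(extent) || any(extent <= 0))
    stop("`extent` must be positive")
  rad2deg(2 * atan(extent / (2 * distance)))
}

#' Scene geometry
#'
#' Bundles the vertical subtended angle, the image height and the derived
#' viewing distance used by every grid and sampling computation.
#'
#' @param alpha_v Vertical subtended angle in degrees, in (0, 180).
#' @param h Image height in pixels.
#' @return An object of class `scene_geometry` with fields `alpha_v`, `h`
#'   and `d` (viewing distance in pixels).
#' @export
#' @examples
#' scene_geometry(60, 1000)
scene_geometry <- function(alpha_v, h) {
  if (length(alpha_v) != 1L || length(h) != 1L)
    stop("`alpha_v` and `h` must be scalars")
  h <- as.integer(h)
  d <- viewing_distance(alpha_v, h)
  structure(list(alpha_v = alpha_v, h = h, d = d), class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat(sprintf("scene geometry: alpha_v = %g deg, h = %d px, d = %.4f px\n",
              x$alpha_v, x$h, x$d))
  invisible(x)
}

#' Angular parameters of one chromatic channel
#'
#' The spatial layout of one channel's sampling stations is governed by the
#' horizontal and vertical interommatidial angles and by the acceptance
#' angle (the full width at half maximum of a station's Gaussian angular
#' sensitivity). Each of the three quantities is a quadratic function of the
#' ring index m (eccentricity), `c0 + m c1 + m^2 c2`; interommatidial angles
#' are additionally clipped into `[phi_min, phi_max]`.
#'
#' @param phi_h,phi_v,rho Numeric vectors of 1 to 3 coefficients
#'   (degrees, degrees/ring, degrees/ring^2); missing coefficients are 0.
#'   In scanning mode only the leading coefficient is used.
#' @param phi_min,phi_max Clamp bounds (degrees) applied to every evaluated
#'   interommatidial angle, `0 < phi_min <= phi_max < 180`.
#' @return An object of class `eye_params`.
#' @export
#' @examples
#' eye_params(phi_h = 1.6, phi_v = 0.9, rho = 2.6) # honeybee
eye_params <- function(phi_h, phi_v, rho, phi_min = 1e-6, phi_max = 90) {
  pad3 <- function(x, name) {
    if (!is.numeric(x) || length(x) < 1L || length(x) > 3L || anyNA(x))
      stop(sprintf("`%s` must be 1 to 3 finite numbers", name))
    c(x, rep(0, 3L - length(x)))
  }
  phi_h <- pad3(phi_h, "phi_h"); phi_v <- pad3(phi_v, "phi_v")
  rho <- pad3(rho, "rho")
  if (phi_h[1] <= 0 || phi_v[1] <= 0)
    stop("leading interommatidial-angle coefficients must be positive")
  if (rho[1] <= 0) stop("leading acceptance-angle coefficient must be positive")
  if (!(phi_min > 0 && phi_min <= phi_max && phi_max < 180))
    stop("clamps must satisfy 0 < phi_min <= phi_max < 180")
  structure(list(phi_h = phi_h, phi_v = phi_v, rho = rho,
                 phi_min = phi_min, phi_max = phi_max),
            class = "eye_params")
}

#' @export
print.eye_params <- function(x, ...) {
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = ", ")
  cat("eye channel parameters (degrees):\n")
  cat("  phi_h:", fmt(x$phi_h), "\n  phi_v:", fmt(x$phi_v), "\n")
  cat("  rho:  ", fmt(x$rho), "\n")
  cat(sprintf("  clamps: [%g, %g]\n", x$phi_min, x$phi_max))
  invisible(x)
}

#' Eye model: mode plus one or three channel parameter sets
#'
#' @param params Either a single [eye_params()] object (shared by all output
#'   channels) or a list of exactly three, in R, G, B order (per-channel
#'   spatial parameters).
#' @param mode `"scanning"` (the eye inspects the image with side-to-side
#'   movements, looking perpendicularly at each station's cell) or
#'   `"fixed"` (a stationary eye on the normal through the image centre).
#' @return An object of class `eye_model` with fields `mode`, `channels`
#'   (a list of 1 or 3 `eye_params`) and `shared` (logical).
#' @export
#' @examples
#' eye_model(eye_params(1.6, 0.9, 2.6), mode = "scanning")
eye_model <- function(params, mode = c("scanning", "fixed")) {
  mode <- match.arg(mode)
  if (inherits(params, "eye_params")) {
    channels <- list(params)
  } else if (is.list(params) && length(params) == 3L &&
             all(vapply(params, inherits, logical(1), "eye_params"))) {
    channels <- params
    names(channels) <- c("R", "G", "B")
  } else {
    stop("`params` must be one eye_params object or a list of exactly three")
  }
  structure(list(mode = mode, channels = channels,
                 shared = length(channels) == 1L),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("eye model: %s mode, %s\n", x$mode,
              if (x$shared) "shared channel parameters"
              else "per-channel (R, G, B) parameters"))
  for (p in x$channels) print(p)
  invisible(x)
}

#' Hexagon spacing of the scanning grid
#'
#' Row and column spacing of the scanning-mode hexagonal grid on the image
#' plane: `2 d tan(phi_V/2)` vertically and `2 d tan(phi_H/2)` horizontally,
#' using the leading (ring-0) interommatidial angles.
#'
#' @param geom A [scene_geometry()].
#' @param params An [eye_params()].
#' @return Named numeric vector `c(vertical = , horizontal = )`, pixels.
#' @export
hexagon_spacings <- function(geom, params) {
  stopifnot(inherits(geom, "scene_geometry"), inherits(params, "eye_params"))
  c(vertical = 2 * geom$d * tan(deg2rad(params$phi_v[1]) / 2),
    horizontal = 2 * geom$d * tan(deg2rad(params$phi_h[1]) / 2))
}

#' Eccentricity-dependent angle
#'
#' Evaluates the quadratic eccentricity model `c0 + m c1 + m^2 c2` at ring
#' index `m` and, when clamp bounds are supplied, clips the result into
#' `[clamp[1], clamp[2]]`. Used for the interommatidial angle between rings
#' `m` and `m + 1` of a fixed-viewpoint grid (clamped) and for the per-ring
#' acceptance angle (unclamped).
#'
#' @param m Ring index (non-negative integer, vectorised).
#' @param coef Numeric vector of 1 to 3 coefficients.
#' @param clamp Optional length-2 numeric `c(min, max)` in degrees.
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' eccentric_angle(3, c(0.9, 0.02, 0.001)) # 0.969
eccentric_angle <- function(m, coef, clamp = NULL) {
  if (any(m < 0) || any(m != floor(m))) stop("`m` must be a non-negative integer")
  coef <- c(coef, rep(0, 3 - length(coef)))[1:3]
  val <- coef[1] + m * coef[2] + m^2 * coef[3]
  if (is.null(clamp)) {
    if (any(val <= 0))
      stop("eccentricity model yields a non-positive angle and no clamp is set")
    return(val)
  }
  pmin(pmax(val, clamp[1]), clamp[2])
}

# cumulative clamped interommatidial angle from ring 0 to n-1 (degrees)
cumulative_angle <- function(n, coef, clamp) {
  if (n == 0) return(0)
  sum(eccentric_angle(0:(n - 1), coef, clamp))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
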