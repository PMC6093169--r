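#' Square-wave grating specification
#'
#' Describes a horizontal black/white stripe pattern of spatial frequency
#' `nu` cycles per degree, rendered into an image that subtends `alpha_v`
#' degrees vertically. Stripes have equal *angular* width: the boundary at
#' angle `theta` from the central row maps to the pixel row `d tan(theta)`
#' away from the image centre. Sampling adequacy is enforced: at least 4
#' pixels per central period and at least 6 periods within the image.
#'
#' @param nu Spatial frequency, cycles per degree (positive).
#' @param alpha_v Vertical subtended angle, degrees; default `n_periods/nu`.
#' @param n_periods Number of grating periods within the image when
#'   `alpha_v` is derived (default 8).
#' @param height,width Image size in pixels.
#' @return An object of class `grating_spec` (also carries the derived
#'   viewing distance `d` and central period in pixels, `period_px`).
#' @export
grating_spec <- function(nu, alpha_v = NULL, n_periods = 8,
                         height = 1000, width = 256) {
  if (nu <= 0) stop("`nu` must be positive")
  if (is.null(alpha_v)) alpha_v <- n_periods / nu
  if (alpha_v >= 180)
    stop("grating would subtend 180 degrees or more; increase `nu` or lower `n_periods`")
  if (nu * alpha_v < 6)
    stop("fewer than 6 grating periods within the image")
  d <- viewing_distance(alpha_v, height)
  period_deg <- 1 / nu
  period_px <- 2 * d * tan(deg2rad(period_deg) / 2)
  if (period_px < 4)
    stop("fewer than 4 pixels per grating period (aliasing guard)")
  structure(list(nu = nu, alpha_v = alpha_v, height = as.integer(height),
                 width = as.integer(width), d = d,
                 period_deg = period_deg, period_px = period_px),
            class = "grating_spec")
}

#' Generate a square-wave grating image
#'
#' @param spec A [grating_spec()].
#' @param phase Phase offset in periods (0 puts a black/white boundary on
#'   the central row).
#' @return Numeric matrix (height x width) of 0/255 values.
#' @export
make_grating <- function(spec, phase = 0) {
  stopifnot(inherits(spec, "grating_spec"))
  y <- (seq_len(spec$height) - 0.5) - spec$height / 2
  theta <- rad2deg(atan(y / spec$d))
  col <- ifelse(((theta / spec$period_deg + phase) %% 1) < 0.5, 255, 0)
  matrix(col, nrow = spec$height, ncol = spec$width)
}

#' Measure modulation of a processed grating
#'
#' Selects the horizontal band of height two grating periods centred on the
#' image's central row (two stripes above and two below the centre line),
#' takes the maximum and minimum intensity over the band, and returns
#' `(Imax - Imin) / (Imax + Imin)`. Intensity of an RGB image is the
#' per-pixel channel mean. An all-black band yields 0 with a warning.
#'
#' @param img Processed grating: matrix, array, or `eye_mosaic`.
#' @param period_px Grating period at the image centre, in pixels (see
#'   `grating_spec()$period_px`).
#' @return Modulation in \[0, 1\].
#' @export
measure_modulation <- function(img, period_px) {
  if (inherits(img, "eye_mosaic")) img <- img$image
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  plane <- apply(img, c(1, 2), mean)
  h <- nrow(plane)
  y <- (seq_len(h) - 0.5) - h / 2
  band <- plane[abs(y) <= period_px, , drop = FALSE]
  imax <- max(band); imin <- min(band)
  if (imax + imin == 0) {
    warning("all-black band: modulation defined as 0")
    return(0)
  }
  (imax - imin) / (imax + imin)
}

#' Analytic Gaussian modulation transfer function
#'
#' Contrast attenuation of a sinusoidal grating of spatial frequency `nu`
#' (cycles/degree) by a Gaussian acceptance profile of full width at half
#' maximum `rho` (degrees): `exp(-3.56 (nu rho)^2)`.
#'
#' @param nu Spatial frequency, cycles per degree (non-negative).
#' @param rho Acceptance angle, degrees (positive).
#' @return Modulation in (0, 1].
#' @export
#' @examples
#' gaussian_mtf(0.25, 2.6)
gaussian_mtf <- function(nu, rho) {
  if (any(nu < 0)) stop("`nu` must be non-negative")
  if (any(rho <= 0)) stop("`rho` must be positive")
  exp(-3.56 * (nu * rho)^2)
}

#' Measured modulation transfer function of a scanning-mode eye
#'
#' For each spatial frequency: builds a square-wave grating subtending
#' `n_periods/nu` degrees, runs it through the scanning pipeline with the
#' given eye parameters, and measures the modulation of the output
#' (see [measure_modulation()]). To avoid phase-locking between the grating
#' and the station grid, `phases` evenly spaced grating phases (plus one
#' seed-controlled random common offset) are processed and the mean
#' modulation is reported together with the per-phase spread.
#'
#' @param params An [eye_params()].
#' @param nu Vector of spatial frequencies, cycles per degree.
#' @param phases Number of grating phases averaged per frequency.
#' @param seed Integer seed for the random common phase offset; `NULL`
#'   leaves the offset at 0.
#' @param n_periods,height,width Grating geometry (see [grating_spec()]).
#' @param trunc Gaussian truncation radius in units of rho.
#' @param verbose Emit per-frequency progress messages.
#' @return An object of class `mtf_curve`: a data frame with columns `nu`,
#'   `modulation` (phase-averaged), `sd` (per-phase spread) and `analytic`
#'   (the Gaussian MTF at the leading acceptance angle).
#' @export
mtf_curve <- function(params, nu, phases = 8, seed = NULL, n_periods = 8,
                      height = 1000, width = 256, trunc = 2,
                      verbose = FALSE) {
  stopifnot(inherits(params, "eye_params"))
  if (is.unsorted(nu, strictly = TRUE))
    stop("`nu` must be strictly increasing")
  base <- 0
  if (!is.null(seed)) {
    set.seed(seed)
    base <- stats::runif(1)
  }
  offs <- (base + seq_len(phases) / phases) %% 1
  rows <- lapply(nu, function(v) {
    spec <- grating_spec(v, n_periods = n_periods,
                         height = height, width = width)
    geom <- scene_geometry(spec$alpha_v, spec$height)
    grid <- build_scanning_grid(geom, params, c(spec$width, spec$height))
    mods <- vapply(offs, function(ph) {
      plane <- make_grating(spec, phase = ph)
      vals <- station_colors(grid, plane, trunc = trunc)
      out <- render_mosaic(grid, vals)
      measure_modulation(out[, , 1], spec$period_px)
    }, numeric(1))
    if (verbose)
      message(sprintf("nu = %g c/deg: modulation %.4f (sd %.4f, %d stations)",
                      v, mean(mods), stats::sd(mods), nrow(grid$stations)))
    data.frame(nu = v, modulation = mean(mods), sd = stats::sd(mods))
  })
  out <- do.call(rbind, rows)
  out$analytic <- gaussian_mtf(out$nu, params$rho[1])
  structure(out, class = c("mtf_curve", "data.frame"),
            rho = params$rho[1])
}

#' Plot a measured MTF curve against the analytic Gaussian
#'
#' @param x An [mtf_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mtf_curve <- function(x, ...) {
  graphics::plot(x$nu, x$modulation, pch = 17, ylim = c(0, 1),
                 xlab = "spatial frequency (cycles/degree)",
                 ylab = "modulation", ...)
  nn <- seq(min(x$nu), max(x$nu), length.out = 200)
  graphics::lines(nn, gaussian_mtf(nn, attr(x, "rho")))
  graphics::legend("topright", bty = "n", pch = c(17, NA), lty = c(NA, 1),
                   legend = c("measured (square-wave gratings)",
                              "Gaussian MTF (sine)"))
  invisible(x)
}

#' Write an MTF curve as a two-column plain-text table
#'
#' @param x An [mtf_curve()].
#' @param path Output path (columns: nu, modulation).
#' @return `path`, invisibly.
#' @export
write_mtf <- function(x, path) {
  utils::write.table(x[, c("nu", "modulation")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
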