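# Independent oracles, deliberately written as naive double loops / closed
# forms so they share no code with the implementation they check.

# Gaussian-weighted station color, no truncation, plain R double loop
oracle_station_color <- function(plane, cx, cy, rho_deg, d,
                                 mode = c("scanning", "fixed"),
                                 x0 = ncol(plane) / 2, y0 = nrow(plane) / 2) {
  mode <- match.arg(mode)
  rho <- rho_deg * pi / 180
  sw <- 0; swc <- 0
  for (j in seq_len(ncol(plane))) {
    for (i in seq_len(nrow(plane))) {
      px <- j - 0.5; py <- i - 0.5
      if (mode == "scanning") {
        a <- atan(sqrt((px - cx)^2 + (py - cy)^2) / d)
      } else {
        va <- c(cx - x0, cy - y0, -d)
        vb <- c(px - x0, py - y0, -d)
        a <- acos(min(1, max(-1, sum(va * vb) /
                               (sqrt(sum(va^2)) * sqrt(sum(vb^2))))))
      }
      w <- exp(-2.77 * (a / rho)^2)
      sw <- sw + w
      swc <- swc + w * plane[i, j]
    }
  }
  swc / sw
}

# brute-force nearest-station assignment, ties to the lowest index
oracle_nn_assign <- function(sx, sy, width, height) {
  out <- matrix(NA_integer_, height, width)
  for (j in seq_len(width)) {
    for (i in seq_len(height)) {
      d2 <- (sx - (j - 0.5))^2 + (sy - (i - 0.5))^2
      out[i, j] <- which(d2 == min(d2))[1]
    }
  }
  out
}

# closed-form modulation of a square-wave grating through a Gaussian
# acceptance profile of FWHM rho: Fourier series of the square wave, each
# harmonic attenuated by the sine-wave Gaussian MTF, evaluated at the stripe
# centre (the band maximum), clipped to [0, 1]
oracle_square_wave_modulation <- function(nu, rho, kmax = 199) {
  k <- seq(1, kmax, by = 2)
  s <- sum((-1)^((k - 1) / 2) / k * exp(-3.56 * (k * nu * rho)^2))
  min(1, 4 / pi * s)
}

# is point p strictly inside convex polygon `poly` (vertex matrix), with a
# margin `eps` away from every edge?
inside_convex <- function(p, poly, eps = 1e-7) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  s <- vapply(seq_len(n), function(k) {
    k2 <- if (k == n) 1L else k + 1L
    e <- poly[k2, ] - poly[k, ]
    v <- p - poly[k, ]
    e[1] * v[2] - e[2] * v[1]
  }, numeric(1))
  all(s > eps) || all(s < -eps)
}

bee_params <- function() eye_params(phi_h = 1.6, phi_v = 0.9, rho = 2.6)
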