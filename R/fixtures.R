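# synthetic test scenes: everything the test-suite and examples feed the
# pipeline is generated here, in code

#' Uniform field
#'
#' @param width,height Image size in pixels.
#' @param value Pixel value (0--255).
#' @param channels 1 (gray) or 3 (RGB).
#' @return Numeric array (height x width x channels).
#' @export
uniform_field <- function(width, height, value = 127, channels = 1) {
  array(value, c(height, width, channels))
}

#' Checkerboard
#'
#' @param width,height Image size in pixels.
#' @param cell Cell edge in pixels.
#' @param lo,hi Values of the two tones.
#' @param channels 1 or 3.
#' @return Numeric array (height x width x channels).
#' @export
checkerboard <- function(width, height, cell = 8, lo = 0, hi = 255,
                         channels = 1) {
  i <- (seq_len(height) - 1) %/% cell
  j <- (seq_len(width) - 1) %/% cell
  m <- ifelse(outer(i, j, "+") %% 2 == 0, hi, lo)
  array(m, c(height, width, channels))
}

#' Two-tone vertical step edge
#'
#' Left half `lo`, right half `hi`; used to probe blur monotonicity.
#'
#' @param width,height Image size in pixels.
#' @param lo,hi Tone values.
#' @return Numeric matrix (height x width).
#' @export
step_edge <- function(width, height, lo = 0, hi = 255) {
  matrix(rep(ifelse(seq_len(width) <= width / 2, lo, hi), each = height),
         height, width)
}

#' Color test card
#'
#' A deterministic RGB scene with smooth gradients and sharp blocks in every
#' channel: R ramps horizontally, G ramps vertically, B carries a coarse
#' checkerboard. Exercises chromatic and spatial structure at once.
#'
#' @param width,height Image size in pixels.
#' @return Numeric array (height x width x 3) on the 0--255 scale.
#' @export
test_card <- function(width, height) {
  a <- array(0, c(height, width, 3))
  a[, , 1] <- matrix(rep(seq(0, 255, length.out = width), each = height),
                     height, width)
  a[, , 2] <- matrix(rep(seq(255, 0, length.out = height), times = width),
                     height, width)
  a[, , 3] <- checkerboard(width, height, cell = max(4, width %/% 8))[, , 1]
  a
}
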