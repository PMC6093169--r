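#' Weighting matrix for filter-photograph recombination
#'
#' Validates a weighting matrix `W` whose entry `w[f, c]` is the weight of
#' gray-scale filter photograph `f` on output channel `c` (R, G, B). Between
#' 1 and 9 photographs are supported; entries are unrestricted finite reals
#' (no sign or normalisation convention is imposed), so recombined values
#' may leave \[0, 255\] and are clipped only at render time.
#'
#' @param w Numeric matrix with one row per input photograph (max 9) and
#'   three columns, or a path to a whitespace-separated plain-text file with
#'   that shape.
#' @return A validated numeric matrix of class `weight_matrix`.
#' @export
#' @examples
#' weight_matrix(diag(3)) # identity: files are the R, G, B planes
weight_matrix <- function(w) {
  if (is.character(w)) {
    if (!file.exists(w)) stop(sprintf("weight-matrix file not found: %s", w))
    w <- as.matrix(utils::read.table(w, header = FALSE))
  }
  w <- unname(as.matrix(w))
  if (!is.numeric(w) || any(!is.finite(w)))
    stop("weight matrix entries must be finite numbers")
  if (ncol(w) != 3L)
    stop("weight matrix must have 3 columns (R, G, B)")
  if (nrow(w) < 1L || nrow(w) > 9L)
    stop("weight matrix must have between 1 and 9 rows (input photographs)")
  structure(w, class = c("weight_matrix", class(w)))
}

#' Write a weighting matrix to a plain-text file
#'
#' @param w A [weight_matrix()] (or coercible matrix).
#' @param path Output path; F rows, 3 whitespace-separated columns.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(w, path) {
  w <- weight_matrix(w)
  utils::write.table(unclass(w), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine per-file station values through the weighting matrix
#'
#' Linear recombination of filter-photograph station values into output
#' channels: channel `c` of station `n` is `sum_f w[f, c] * values[n, f]`.
#' No clipping happens here (that is the renderer's job).
#'
#' @param values Numeric matrix of station values (stations x files), or a
#'   length-F vector for a single station.
#' @param w A [weight_matrix()] with `F` rows.
#' @return Stations x 3 matrix of (R, G, B) values (a length-3 vector if
#'   `values` was a vector).
#' @export
combine_channels <- function(values, w) {
  w <- weight_matrix(w)
  vec <- is.null(dim(values))
  values <- rbind(values)
  if (ncol(values) != nrow(w))
    stop(sprintf("got %d per-file values per station but W has %d rows",
                 ncol(values), nrow(w)))
  out <- values %*% unclass(w)
  colnames(out) <- c("R", "G", "B")
  if (vec) out[1, ] else out
}

# collapse a (possibly RGB-encoded) gray image to one plane; a nominally
# gray RGB file must have channels equal within `tol` levels
as_gray_plane <- function(img, tol = 1, what = "input") {
  if (inherits(img, "eye_image")) img <- img$data
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  if (length(dim(img)) == 3L && dim(img)[3] == 3L) {
    dmax <- max(abs(img[, , 1] - img[, , 2]), abs(img[, , 1] - img[, , 3]))
    if (dmax > tol)
      stop(sprintf(
        "%s is not gray-scale: RGB channels differ by up to %.1f levels",
        what, dmax))
    return((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  }
  stop("expected a gray-scale image")
}
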