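#' Build the scanning-mode sampling grid
#'
#' Lays sampling stations on a hexagonally packed lattice over the image:
#' horizontal rows spaced `2 d tan(phi_V/2)` apart, stations within a row
#' spaced `2 d tan(phi_H/2)` apart, alternate rows offset by half the
#' horizontal spacing (pointy-top hexagonal cells). One station is anchored
#' at the exact image centre. Stations are kept when their cell contains at
#' least one pixel centre; every pixel centre is assigned to its nearest
#' station (ties to the lowest station id). All stations carry the ring-0
#' acceptance angle.
#'
#' @param geom A [scene_geometry()]; its `h` must equal the image height.
#' @param params An [eye_params()].
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @return A `sampling_grid` object: `stations` (data frame with `id`, `x`,
#'   `y`, `ring`, `rho`, `n_pixels`), `assignment` (height x width integer
#'   matrix of station ids), `mode`, `geom`, `params`, `spacing`.
#' @export
#' @examples
#' g <- build_scanning_grid(scene_geometry(60, 64), eye_params(8, 8, 10),
#'                          c(64, 64))
#' nrow(g$stations)
build_scanning_grid <- function(geom, params, image_size) {
  stopifnot(inherits(geom, "scene_geometry"), inherits(params, "eye_params"))
  image_size <- as.integer(image_size)
  w <- image_size[1]; h <- image_size[2]
  if (h != geom$h)
    stop("image height does not match the scene geometry")
  sp <- hexagon_spacings(geom, params)
  sv <- sp[["vertical"]]; sh <- sp[["horizontal"]]
  if (min(sv, sh) < 1)
    warning("grid spacing below one pixel: output is only a slightly blurred input")
  cx0 <- w / 2; cy0 <- h / 2
  jr <- ceiling((max(cy0, h - cy0) + sv) / sv)
  rows <- -jr:jr
  st <- vector("list", length(rows))
  for (ii in seq_along(rows)) {
    j <- rows[ii]
    cy <- cy0 + j * sv
    if (cy < -sv || cy > h + sv) next
    off <- if (j %% 2 == 0) 0 else sh / 2
    kr <- ceiling((max(cx0, w - cx0) + sh) / sh)
    ks <- -kr:kr
    cx <- cx0 + off + ks * sh
    keep <- cx >= -sh & cx <= w + sh
    if (!any(keep)) next
    st[[ii]] <- data.frame(x = cx[keep], y = cy, ring = 0L)
  }
  st <- do.call(rbind, st)
  new_sampling_grid(st, params$rho[1], w, h, "scanning", geom, params,
                    spacing = c(vertical = sv, horizontal = sh),
                    drop_empty = TRUE)
}

#' Build the fixed-viewpoint sampling grid
#'
#' A stationary eye on the normal through the image centre sees its
#' ommatidial axes projected onto the photograph as concentric rings: the
#' central station sits at the image centre and ring `n` carries `6 n`
#' stations on an axis-aligned ellipse with horizontal radius
#' `d tan(sum phi_Hm)` and vertical radius `d tan(sum phi_Vm)` (sums of the
#' clamped eccentricity-model angles over `m = 0 .. n-1`). Stations are
#' evenly spaced in the ellipse parameter, steps of `360 / (6 n)` degrees
#' starting at 12 o'clock and moving clockwise. Rings are added until the
#' ellipse encloses the whole image, the cumulative angle reaches 90 degrees
#' (the planar projection diverges there; the grid is then truncated with a
#' warning), or `max_rings` is hit. Each ring `n` carries the acceptance
#' angle `rho0 + n rho1 + n^2 rho2`. All constructed stations are retained
#' (peripheral ones may own no pixels); every pixel centre is assigned to
#' its nearest station as in scanning mode.
#'
#' @inheritParams build_scanning_grid
#' @param max_rings Optional cap on the number of rings.
#' @return A `sampling_grid` object (see [build_scanning_grid()]).
#' @export
build_fixed_grid <- function(geom, params, image_size, max_rings = NULL) {
  stopifnot(inherits(geom, "scene_geometry"), inherits(params, "eye_params"))
  image_size <- as.integer(image_size)
  w <- image_size[1]; h <- image_size[2]
  if (h != geom$h)
    stop("image height does not match the scene geometry")
  d <- geom$d
  cx0 <- w / 2; cy0 <- h / 2
  clamp <- c(params$phi_min, params$phi_max)
  st <- list(data.frame(x = cx0, y = cy0, ring = 0L))
  cumh <- 0; cumv <- 0; n <- 0L
  truncated <- FALSE
  repeat {
    if (!is.null(max_rings) && n >= max_rings) break
    cumh_next <- cumh + eccentric_angle(n, params$phi_h, clamp)
    cumv_next <- cumv + eccentric_angle(n, params$phi_v, clamp)
    if (cumh_next >= 90 || cumv_next >= 90) {
      truncated <- TRUE
      break
    }
    n <- n + 1L
    cumh <- cumh_next; cumv <- cumv_next
    rh <- d * tan(deg2rad(cumh))
    rv <- d * tan(deg2rad(cumv))
    tt <- deg2rad(360 / (6 * n)) * (0:(6 * n - 1))
    st[[n + 1L]] <- data.frame(x = cx0 + rh * sin(tt),
                               y = cy0 - rv * cos(tt),
                               ring = n)
    encloses <- ((w / 2) / rh)^2 + ((h / 2) / rv)^2 <= 1
    if (is.null(max_rings) && encloses) break
  }
  if (truncated && is.null(max_rings))
    warning(sprintf(paste0("fixed-viewpoint grid truncated after %d ring(s): ",
                           "cumulative angle reached 90 degrees before the ",
                           "ellipse covered the image"), n))
  st <- do.call(rbind, st)
  rho <- eccentric_angle(st$ring, params$rho)
  new_sampling_grid(st, rho, w, h, "fixed", geom, params,
                    n_rings = n, drop_empty = FALSE)
}

# shared grid finalisation: tessellation, pruning, station table
new_sampling_grid <- function(st, rho, w, h, mode, geom, params,
                              spacing = NULL, n_rings = NULL,
                              drop_empty = FALSE) {
  if (anyDuplicated(st[, c("x", "y")]))
    stop("duplicate station centres")
  assignment <- tessellate_stations(st$x, st$y, w, h)
  counts <- tabulate(assignment, nbins = nrow(st))
  rho <- rep_len(rho, nrow(st))
  if (drop_empty && any(counts == 0L)) {
    keep <- counts > 0L
    st <- st[keep, , drop = FALSE]
    rho <- rho[keep]
    assignment[] <- match(assignment, which(keep))
    counts <- counts[keep]
  }
  stations <- data.frame(id = seq_len(nrow(st)), x = st$x, y = st$y,
                         ring = st$ring, rho = rho, n_pixels = counts)
  structure(list(stations = stations, assignment = assignment, mode = mode,
                 geom = geom, params = params, spacing = spacing,
                 n_rings = n_rings),
            class = "sampling_grid")
}

#' Assign pixel centres to the nearest station (Voronoi tessellation)
#'
#' Every pixel centre (pixel in column j, row i has centre `(j-0.5, i-0.5)`;
#' origin top-left, y downwards) is assigned to the station centre nearest
#' in the Euclidean metric, i.e. to the Voronoi region whose boundaries are
#' the perpendicular bisectors of segments joining neighbouring centres.
#' Equidistant pixels go to the lowest station id, for determinism.
#'
#' @param x,y Station centre coordinates (equal length, no duplicates).
#' @param width,height Image size in pixels.
#' @return `height` x `width` integer matrix of 1-based station indices.
#' @export
tessellate_stations <- function(x, y, width, height) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("`x` and `y` must be non-empty and of equal length")
  if (anyDuplicated(cbind(x, y))) stop("duplicate station centres")
  cpp_nn_assign(as.numeric(x), as.numeric(y),
                as.integer(width), as.integer(height))
}

#' Polygonal cells of a sampling grid
#'
#' Explicit cell polygons: each station's cell is its Voronoi region,
#' obtained by clipping the image rectangle with the perpendicular-bisector
#' half-plane towards every other station (only the relevant neighbours are
#' visited). Intended for inspection and plotting of moderate grids; the
#' rendering pipeline itself uses the exact pixel assignment of
#' [tessellate_stations()].
#'
#' @param grid A `sampling_grid`.
#' @return A list with one two-column vertex matrix (x, y, counter-clockwise
#'   in image coordinates) per station; stations whose cell lies entirely
#'   outside the image get a 0-row matrix.
#' @export
station_cells <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  x <- grid$stations$x; y <- grid$stations$y
  w <- ncol(grid$assignment); h <- nrow(grid$assignment)
  n <- length(x)
  rect <- cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
  lapply(seq_len(n), function(i) {
    poly <- rect
    ord <- order((x - x[i])^2 + (y - y[i])^2)
    for (j in ord) {
      if (j == i) next
      if (nrow(poly) == 0L) break
      dij2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
      # if even the farthest remaining vertex is nearer than the bisector,
      # no later (more distant) station can cut the cell further
      vmax2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
      if (dij2 / 4 > vmax2) break
      poly <- clip_halfplane(poly, c(x[i], y[i]), c(x[j], y[j]))
    }
    poly
  })
}

# Sutherland-Hodgman clip of convex polygon `poly` to the half-plane of
# points no farther from a than from b (the a-side of the bisector)
clip_halfplane <- function(poly, a, b) {
  ux <- b[1] - a[1]; uy <- b[2] - a[2]
  mx <- (a[1] + b[1]) / 2; my <- (a[2] + b[2]) / 2
  s <- (poly[, 1] - mx) * ux + (poly[, 2] - my) * uy  # <= 0 kept
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- poly[k, ]; p2 <- poly[k2, ]
    in1 <- s[k] <= 0; in2 <- s[k2] <= 0
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      t <- s[k] / (s[k] - s[k2])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

#' Export cell polygons as plain text
#'
#' Writes one polygon per line: the station id followed by interleaved
#' `x y` vertex coordinates, whitespace-separated.
#'
#' @param grid A `sampling_grid`.
#' @param path Output text file path.
#' @return `path`, invisibly.
#' @export
export_cells <- function(grid, path) {
  cells <- station_cells(grid)
  lines <- vapply(seq_along(cells), function(i) {
    v <- cells[[i]]
    paste(c(i, format(as.vector(t(v)), trim = TRUE)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("sampling grid (%s mode): %d stations, %d x %d px\n",
              x$mode, nrow(x$stations), ncol(x$assignment), nrow(x$assignment)))
  if (!is.null(x$spacing))
    cat(sprintf("  spacing: %.3f px vertical, %.3f px horizontal\n",
                x$spacing[["vertical"]], x$spacing[["horizontal"]]))
  if (!is.null(x$n_rings))
    cat(sprintf("  rings: %d (stations with pixels: %d)\n", x$n_rings,
                sum(x$stations$n_pixels > 0)))
  invisible(x)
}
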