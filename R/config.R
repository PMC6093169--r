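#' Parse a run configuration file
#'
#' Reads the documented key=value configuration format (fail-closed: every
#' unknown key is an error, with the offending line number). Blank lines and
#' `#` comments are ignored.
#'
#' Keys:
#' \describe{
#'   \item{version}{Required; currently `1`.}
#'   \item{mode}{`scanning` or `fixed`.}
#'   \item{alpha_v}{Vertical subtended angle, degrees, in (0, 180).}
#'   \item{input}{Single color/gray input image path (PNG/JPG/TIFF/BMP).}
#'   \item{files}{Comma-separated list of up to nine gray-scale filter
#'     photographs (mutually exclusive with `input`; requires `weights`).}
#'   \item{weights}{Path to the plain-text weighting matrix (F rows, 3
#'     columns).}
#'   \item{output}{Output image path (written in the input's format).}
#'   \item{phi_h, phi_v, rho}{1--3 numbers each: shared channel parameters
#'     (degrees, degrees/ring, degrees/ring^2).}
#'   \item{phi_h_r, phi_v_r, rho_r, ..._g, ..._b}{Per-channel parameter
#'     sets; all nine keys must be present and replace the shared trio.}
#'   \item{phi_min, phi_max}{Optional interommatidial clamp bounds
#'     (degrees); defaults 1e-6 and 90.}
#' }
#'
#' @param path Path to a configuration text file.
#' @return An object of class `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  kv <- list(); lineno <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (grepl("^\\s*$", ln)) next
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3L)
      stop(sprintf("%s:%d: cannot parse line: %s", path, i, trimws(lines[i])))
    key <- m[2]
    if (!is.null(kv[[key]]))
      stop(sprintf("%s:%d: duplicate key '%s'", path, i, key))
    kv[[key]] <- m[3]
    lineno[[key]] <- i
  }
  known <- c("version", "mode", "alpha_v", "input", "files", "weights",
             "output", "phi_h", "phi_v", "rho", "phi_min", "phi_max",
             paste0(rep(c("phi_h_", "phi_v_", "rho_"), 3),
                    rep(c("r", "g", "b"), each = 3)))
  for (key in names(kv))
    if (!key %in% known)
      stop(sprintf("%s:%d: unknown key '%s'", path, lineno[[key]], key))
  ctx <- function(key) sprintf("%s:%d", path, lineno[[key]])
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop(sprintf("%s: missing required key '%s'", path, key))
    kv[[key]]
  }
  nums <- function(key, n_ok) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]]))
    if (anyNA(v) || !length(v) %in% n_ok)
      stop(sprintf("%s: key '%s' must be %s number(s)", ctx(key), key,
                   paste(n_ok, collapse = " to ")))
    v
  }
  if (need("version") != "1")
    stop(sprintf("%s: unsupported config version '%s'", ctx("version"),
                 kv$version))
  mode <- need("mode")
  if (!mode %in% c("scanning", "fixed"))
    stop(sprintf("%s: mode must be 'scanning' or 'fixed'", ctx("mode")))
  need("alpha_v")
  alpha_v <- nums("alpha_v", 1)
  if (alpha_v <= 0 || alpha_v >= 180)
    stop(sprintf("%s: alpha_v must lie strictly between 0 and 180 degrees",
                 ctx("alpha_v")))
  output <- need("output")
  image_format(output)
  input <- kv$input; files <- kv$files; weights <- kv$weights
  if (is.null(input) == is.null(files))
    stop(sprintf("%s: exactly one of 'input' or 'files' must be given", path))
  if (!is.null(input)) {
    image_format(input) # errors on unsupported extensions
    if (!is.null(weights))
      stop(sprintf("%s: 'weights' requires 'files'", ctx("weights")))
  } else {
    files <- trimws(strsplit(files, ",")[[1]])
    if (length(files) < 1L || length(files) > 9L)
      stop(sprintf("%s: between 1 and 9 input files are supported, got %d",
                   ctx("files"), length(files)))
    for (f in files) image_format(f)
    if (is.null(weights))
      stop(sprintf("%s: 'files' requires a 'weights' matrix path", path))
  }
  phi_min <- if (is.null(kv$phi_min)) 1e-6 else nums("phi_min", 1)
  phi_max <- if (is.null(kv$phi_max)) 90 else nums("phi_max", 1)
  per_keys <- paste0(rep(c("phi_h_", "phi_v_", "rho_"), 3),
                     rep(c("r", "g", "b"), each = 3))
  has_per <- vapply(per_keys, function(k) !is.null(kv[[k]]), logical(1))
  has_shared <- vapply(c("phi_h", "phi_v", "rho"),
                       function(k) !is.null(kv[[k]]), logical(1))
  mk <- function(h, v, r) eye_params(h, v, r, phi_min = phi_min,
                                     phi_max = phi_max)
  if (all(has_per)) {
    if (any(has_shared))
      stop(sprintf("%s: give shared or per-channel parameters, not both", path))
    params <- list(R = mk(nums("phi_h_r", 1:3), nums("phi_v_r", 1:3),
                          nums("rho_r", 1:3)),
                   G = mk(nums("phi_h_g", 1:3), nums("phi_v_g", 1:3),
                          nums("rho_g", 1:3)),
                   B = mk(nums("phi_h_b", 1:3), nums("phi_v_b", 1:3),
                          nums("rho_b", 1:3)))
  } else if (any(has_per)) {
    stop(sprintf("%s: per-channel parameters require all nine keys (%s)",
                 path, paste(per_keys[!has_per], collapse = ", ")))
  } else {
    if (!all(has_shared))
      stop(sprintf("%s: missing required key(s): %s", path,
                   paste(c("phi_h", "phi_v", "rho")[!has_shared],
                         collapse = ", ")))
    params <- list(all = mk(nums("phi_h", 1:3), nums("phi_v", 1:3),
                            nums("rho", 1:3)))
  }
  structure(list(version = 1L, mode = mode, alpha_v = alpha_v,
                 input = input, files = files, weights = weights,
                 output = output, params = params),
            class = "run_config")
}

#' Write a run configuration file
#'
#' Inverse of [parse_config()]: `parse_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  out <- c("version = 1",
           paste("mode =", cfg$mode),
           paste("alpha_v =", num(cfg$alpha_v)))
  if (!is.null(cfg$input)) {
    out <- c(out, paste("input =", cfg$input))
  } else {
    out <- c(out, paste("files =", paste(cfg$files, collapse = ", ")),
             paste("weights =", cfg$weights))
  }
  out <- c(out, paste("output =", cfg$output))
  p1 <- cfg$params[[1]]
  if (length(cfg$params) == 1L) {
    out <- c(out, paste("phi_h =", num(p1$phi_h)),
             paste("phi_v =", num(p1$phi_v)),
             paste("rho =", num(p1$rho)))
  } else {
    for (ch in c("r", "g", "b")) {
      p <- cfg$params[[toupper(ch)]]
      out <- c(out, paste0("phi_h_", ch, " = ", num(p$phi_h)),
               paste0("phi_v_", ch, " = ", num(p$phi_v)),
               paste0("rho_", ch, " = ", num(p$rho)))
    }
  }
  out <- c(out, paste("phi_min =", num(p1$phi_min)),
           paste("phi_max =", num(p1$phi_max)))
  writeLines(out, path)
  invisible(path)
}

#' Execute one run configuration
#'
#' Runs the pipeline described by a configuration (file or parsed object),
#' writes the output image in the input image's format, and writes a copy of
#' the effective configuration beside the output with the output's base name
#' and a `.txt` extension, so the parameters behind every output image can
#' always be recovered.
#'
#' @param cfg A `run_config` or a path to a configuration file.
#' @param trunc Gaussian truncation radius (see [station_colors()]).
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with `output` (image path), `provenance`
#'   (config copy path) and the `eye_mosaic`.
#' @export
run_config <- function(cfg, trunc = 2, verbose = FALSE) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  eye <- eye_model(if (length(cfg$params) == 1L) cfg$params[[1]] else
    unname(cfg$params), mode = cfg$mode)
  if (!is.null(cfg$input)) {
    img <- read_image(cfg$input)
    fmt <- img$format
    mos <- eye_view(img, eye, cfg$alpha_v, trunc = trunc, verbose = verbose)
  } else {
    fmt <- image_format(cfg$files[[1]])
    mos <- eye_view_files(as.list(cfg$files), weight_matrix(cfg$weights),
                          eye, cfg$alpha_v, trunc = trunc, verbose = verbose)
  }
  out_fmt <- image_format(cfg$output)
  if (out_fmt != fmt)
    warning(sprintf(
      "output written in the input format (%s) despite '%s' extension",
      fmt, out_fmt))
  write_image(mos$image, cfg$output, format = fmt)
  prov <- paste0(tools::file_path_sans_ext(cfg$output), ".txt")
  write_config(cfg, prov)
  if (verbose) message(sprintf("wrote %s (+ %s)", cfg$output, prov))
  invisible(list(output = cfg$output, provenance = prov, mosaic = mos))
}

#' Run several configurations in batch
#'
#' Each configuration is run independently; a failing run is reported and
#' does not abort the remaining runs.
#'
#' @param paths Character vector of configuration file paths (may be empty).
#' @param trunc,verbose Passed to [run_config()].
#' @return Data frame with one row per configuration: `config`, `output`,
#'   `ok`, `message`.
#' @export
run_batch <- function(paths, trunc = 2, verbose = FALSE) {
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      r <- run_config(p, trunc = trunc, verbose = verbose)
      data.frame(config = p, output = r$output, ok = TRUE, message = "")
    }, error = function(e) {
      warning(sprintf("run failed for %s: %s", p, conditionMessage(e)),
              call. = FALSE)
      data.frame(config = p, output = NA_character_, ok = FALSE,
                 message = conditionMessage(e))
    })
    res
  })
  if (!length(rows))
    return(data.frame(config = character(), output = character(),
                      ok = logical(), message = character()))
  do.call(rbind, rows)
}
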