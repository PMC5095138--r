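# Image and annotation I/O, configuration files.

#' Load an image as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF file. Color images are converted to grayscale with the
#' classic luminance weights (0.299 R + 0.587 G + 0.114 B); an alpha channel
#' is dropped. Bit depths other than 8 are rescaled linearly to 0-255.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix with intensities 0-255, indexed `[row, col]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for: ", path, " (PNG/TIFF only)")
  )
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3L]
    raw <- if (nch >= 3L) {
      0.299 * raw[, , 1L] + 0.587 * raw[, , 2L] + 0.114 * raw[, , 3L]
    } else raw[, , 1L]
  }
  raw * 255
}

#' Write a grayscale matrix or RGB array as PNG
#'
#' @param image Numeric matrix (0-255) or `H x W x 3` array in 0-1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  if (is.matrix(image)) image <- pmin(pmax(image / 255, 0), 1)
  png::writePNG(image, path)
  invisible(path)
}

#' Write / read a detections CSV
#'
#' Comma-separated, UTF-8, mandatory header `x,y,scale,core_mean,min_contrast`,
#' "." decimal separator, floats with 2 decimals -- a bit-exact contract so
#' that identical runs produce byte-identical files.
#'
#' @param detections Detection data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the detections data frame (reader).
#' @export
write_detections <- function(detections, path) {
  cols <- c("x", "y", "scale", "core_mean", "min_contrast")
  out <- detections[, cols, drop = FALSE]
  for (cl in cols) out[[cl]] <- sprintf("%.2f", out[[cl]])
  out[out == "NA"] <- ""
  writeLines(c(paste(cols, collapse = ","),
               apply(out, 1L, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a reference-annotation CSV
#'
#' Header `x,y` plus optional `size` (dot height in pixels).
#'
#' @param reference Reference data frame with `x`, `y` and optionally `size`.
#' @param path File path.
#' @return `path` invisibly (writer); the reference data frame (reader).
#' @export
write_reference <- function(reference, path) {
  cols <- intersect(c("x", "y", "size"), names(reference))
  out <- reference[, cols, drop = FALSE]
  for (cl in cols) out[[cl]] <- sprintf("%.2f", out[[cl]])
  writeLines(c(paste(cols, collapse = ","),
               apply(out, 1L, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  ref <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(ref))) {
    stop("reference CSV must have columns x,y[,size]: ", path)
  }
  ref
}

#' Default run configuration
#'
#' All detector and evaluation parameters with their package defaults, as a
#' named list suitable for [write_config()].
#'
#' @param ... Overrides, e.g. `fppl_config(th2 = 10)`.
#' @return Named list.
#' @export
fppl_config <- function(...) {
  cfg <- list(
    detector = "fppl",
    gap_width = 2L, th1 = 100, th2 = 30,
    scales = c(2, 1, 0.5), dedup_radius = 4,
    bpl_threshold = 60, min_area = 3L, max_area = 200L,
    exclude_on_edges = FALSE, include_holes = FALSE,
    rolling_radius = 20,
    annulus_inner = 3, annulus_outer = 8,
    tolerance = 5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Write / read a run configuration file (YAML key-value text)
#'
#' @param config Named list as from [fppl_config()].
#' @param path File path.
#' @return `path` invisibly (writer); the config list (reader).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(fppl_config, cfg)
}

#' Write a fixture bundle to a directory
#'
#' Writes `image.png`, `reference.csv` and a `provenance.yaml` sidecar that
#' suffices to regenerate the fixture bit-exactly.
#'
#' @param fixture An `fppl_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fppl_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_image(fixture$image, file.path(dir, "image.png"))
  write_reference(fixture$reference, file.path(dir, "reference.csv"))
  yaml::write_yaml(fixture$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
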