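# FpPL whole-image scanning, hit clustering and the multi-scale strategy.

# Mean of `offsets` (k x 2 matrix of (dr, dc)) around every valid center of
# `img`, vectorized as shifted submatrix sums. Valid centers are those where
# the full pattern square fits: rows (h+1)..(H-h), cols (w side) likewise.
offset_mean <- function(img, offsets, h) {
  H <- nrow(img); W <- ncol(img)
  nr <- H - 2L * h; nc <- W - 2L * h
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1L]; dc <- offsets[k, 2L]
    acc <- acc + img[(h + 1L + dr):(H - h + dr), (h + 1L + dc):(W - h + dc)]
  }
  acc / nrow(offsets)
}

# Core mean and minimum core-minus-periphery contrast at every valid center.
# Returns matrices indexed by (center_row - h, center_col - h).
pattern_response <- function(img, pattern) {
  h <- pattern$half
  if (nrow(img) < pattern$side || ncol(img) < pattern$side) {
    stop(sprintf("image (%dx%d) is smaller than the %dx%d pattern",
                 nrow(img), ncol(img), pattern$side, pattern$side))
  }
  core <- offset_mean(img, pattern$core, h)
  pmax_per <- NULL
  for (p in pattern$periphery) {
    m <- offset_mean(img, p, h)
    pmax_per <- if (is.null(pmax_per)) m else pmax(pmax_per, m)
  }
  list(core_mean = core, min_contrast = core - pmax_per, half = h)
}

#' Scan a whole image with the flexible pattern
#'
#' Slides the pattern pixel by pixel over every position where it fits
#' entirely inside the image (a blind margin of `(side-1)/2` pixels remains
#' at each border) and evaluates the core-vs-periphery discriminant at each
#' center.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @inheritParams evaluate_discriminant
#' @return A data frame with one row per satisfying center: `x`, `y` (1-based
#'   column/row), `core_mean`, `min_contrast` (the smallest of the eight
#'   core-minus-periphery differences).
#' @seealso [detect_multiscale()] for the full detector.
#' @export
scan_image <- function(image, pattern, th1, th2) {
  stopifnot(inherits(pattern, "fppl_pattern"))
  check_thresholds(th1, th2)
  resp <- pattern_response(image, pattern)
  hit <- resp$core_mean > th1 & resp$min_contrast > th2
  idx <- which(hit, arr.ind = TRUE)
  data.frame(
    x = as.numeric(idx[, 2L] + resp$half),
    y = as.numeric(idx[, 1L] + resp$half),
    core_mean = resp$core_mean[idx],
    min_contrast = resp$min_contrast[idx]
  )
}

# 8-connected components of a set of pixels given as a data frame with
# integer x/y. Returns an integer component id per row.
pixel_components <- function(x, y) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  key <- paste(x, y)
  id <- seq_len(n)
  edges <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- match(paste(x + d[1L], y + d[2L]), key)
    ok <- !is.na(nb)
    if (any(ok)) edges <- rbind(edges, cbind(id[ok], nb[ok]))
  }
  if (is.null(edges)) return(id)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Merge adjacent hit pixels into particle detections
#'
#' Groups the satisfying pixels of one scan into 8-connected components; each
#' component becomes one detection positioned at the component centroid, with
#' `core_mean` and `min_contrast` taken from the component pixel with the
#' largest `min_contrast`.
#'
#' @param hits Data frame as returned by [scan_image()].
#' @param scale Scale factor to record in the output (provenance only).
#' @return A detection data frame: `x`, `y`, `scale`, `core_mean`,
#'   `min_contrast`, one row per particle.
#' @export
cluster_hits <- function(hits, scale = 1.0) {
  if (nrow(hits) == 0L) return(empty_detections())
  comp <- pixel_components(round(hits$x), round(hits$y))
  out <- lapply(split(seq_len(nrow(hits)), comp), function(i) {
    best <- i[which.max(hits$min_contrast[i])]
    data.frame(x = mean(hits$x[i]), y = mean(hits$y[i]), scale = scale,
               core_mean = hits$core_mean[best],
               min_contrast = hits$min_contrast[best])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
             core_mean = numeric(0), min_contrast = numeric(0))
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Separable 1-D area resampling along rows: piecewise-constant integral of
# each column, averaged over equal-width output cells.
area_resample_rows <- function(m, new_n) {
  n <- nrow(m)
  if (new_n == n) return(m)
  s <- n / new_n
  cs <- rbind(0, apply(m, 2L, cumsum))
  S <- function(t) {           # integral of the piecewise-constant profile
    i <- pmin(floor(t), n - 1e-9); i <- floor(i)
    fr <- t - i
    cs[i + 1L, , drop = FALSE] + fr * m[pmin(i + 1L, n), , drop = FALSE]
  }
  b <- (0:new_n) * s
  (S(b[-1L]) - S(b[-(new_n + 1L)])) / s
}

# Bilinear sampling along rows at pixel-center-aligned positions.
bilinear_resample_rows <- function(m, new_n) {
  n <- nrow(m)
  if (new_n == n) return(m)
  src <- (seq_len(new_n) - 0.5) * (n / new_n) + 0.5
  src <- pmin(pmax(src, 1), n)
  i0 <- pmin(floor(src), n - 1L); i0 <- pmax(i0, 1L)
  fr <- src - i0
  m[i0, , drop = FALSE] * (1 - fr) + m[i0 + 1L, , drop = FALSE] * fr
}

#' Rescale a grayscale image
#'
#' Resizes to `round(dim * factor)` (rounding half away from zero), using
#' bilinear interpolation when enlarging and area (local-mean) averaging when
#' shrinking, applied separably. Pixel centers are aligned between grids:
#' output pixel `i` samples input position `(i - 0.5) / factor + 0.5`.
#' Intensities stay within the input range; constant images stay constant.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param factor Positive scale factor (2 doubles each dimension).
#' @return The resized matrix.
#' @export
rescale_image <- function(image, factor) {
  if (length(factor) != 1L || is.na(factor) || factor <= 0) {
    stop("'factor' must be a single positive number")
  }
  if (factor == 1) return(image)
  new_h <- as.integer(round_half_up(nrow(image) * factor))
  new_w <- as.integer(round_half_up(ncol(image) * factor))
  if (new_h < 1L || new_w < 1L) stop("rescaled image would be empty")
  f <- if (factor > 1) bilinear_resample_rows else area_resample_rows
  out <- f(image, new_h)
  out <- t(f(t(out), new_w))
  out
}

#' Detect particles with the multi-scale flexible-pattern detector
#'
#' The full FpPL detector: the image is rescaled to each factor in `scales`,
#' scanned with the pattern, hits are clustered into per-scale detections,
#' detection coordinates are mapped back to original-image coordinates
#' (`orig = (pos - 0.5) / scale + 0.5`), and detections closer than
#' `dedup_radius` across scales are merged so each physical particle yields
#' at most one detection. When duplicates merge, the detection from the scale
#' closest to 1.0 is kept (ties broken toward the larger scale). Scanning
#' smaller-scale copies labels particles too large for the pattern in the
#' original image; enlarged copies recover particles below the original
#' detection resolution.
#'
#' @inheritParams scan_image
#' @param scales Numeric vector of positive scale factors
#'   (default `c(2, 1, 0.5)`, i.e. 200% down to 50%).
#' @param dedup_radius Merge radius in original-image pixels (default 4).
#' @return A detection data frame (`x`, `y`, `scale`, `core_mean`,
#'   `min_contrast`) in original-image coordinates.
#' @examples
#' img <- matrix(0, 60, 60); img[29:31, 29:31] <- 255
#' detect_multiscale(img, build_pattern(2), th1 = 100, th2 = 30)
#' @export
detect_multiscale <- function(image, pattern = build_pattern(2),
                              th1 = 100, th2 = 30,
                              scales = c(2, 1, 0.5), dedup_radius = 4) {
  stopifnot(inherits(pattern, "fppl_pattern"))
  if (length(scales) == 0L || any(is.na(scales)) || any(scales <= 0)) {
    stop("'scales' must be a non-empty vector of positive factors")
  }
  if (dedup_radius < 0) stop("'dedup_radius' must be >= 0")

  per_scale <- list()
  n_skipped <- 0L
  for (s in scales) {
    dims <- round_half_up(dim(image) * s)
    if (any(dims < pattern$side)) {
      warning(sprintf("scale %.3g skipped: rescaled image (%dx%d) smaller than pattern",
                      s, dims[1L], dims[2L]))
      n_skipped <- n_skipped + 1L
      next
    }
    scaled <- if (s == 1) image else rescale_image(image, s)
    det <- cluster_hits(scan_image(scaled, pattern, th1, th2), scale = s)
    if (nrow(det) > 0L) {
      det$x <- (det$x - 0.5) / s + 0.5
      det$y <- (det$y - 0.5) / s + 0.5
      det$x <- pmin(pmax(det$x, 1), ncol(image))
      det$y <- pmin(pmax(det$y, 1), nrow(image))
    }
    per_scale[[length(per_scale) + 1L]] <- det
  }
  if (n_skipped == length(scales)) stop("all scales were skipped; image too small")
  dets <- do.call(rbind, c(per_scale, list(empty_detections())))
  dedup_detections(dets, dedup_radius)
}

# Keep at most one detection per physical particle: order by preference
# (|scale-1| ascending, then larger scale), greedily keep detections not
# within `radius` of an already kept one.
dedup_detections <- function(dets, radius) {
  n <- nrow(dets)
  if (n <= 1L) return(dets)
  ord <- order(abs(dets$scale - 1), -dets$scale)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in ord) {
    if (length(kx) == 0L ||
        min((kx - dets$x[i])^2 + (ky - dets$y[i])^2) > radius^2) {
      keep[i] <- TRUE
      kx <- c(kx, dets$x[i]); ky <- c(ky, dets$y[i])
    }
  }
  out <- dets[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
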