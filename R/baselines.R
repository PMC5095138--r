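# Baseline detectors: threshold-based particle labeling (BPL) with optional
# preprocessors, and multi-template matching (MTM).

#' Basic particle labeling (threshold + connected components + area filter)
#'
#' The ImageJ-style baseline: binarize the image at a global brightness
#' threshold (`pixel > threshold` is foreground), extract 8-connected
#' components, keep those whose area lies in `[min_area, max_area]`
#' (default 3-200 px), and return component centroids as detections.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param threshold Binarization threshold, 0-255 (default 60).
#' @param min_area,max_area Component area bounds in pixels.
#' @param exclude_on_edges Drop components touching the image border
#'   (default `FALSE`).
#' @param include_holes Fill interior holes before measuring area
#'   (default `FALSE`).
#' @return A detection data frame (`x`, `y`, `scale` = 1, `core_mean` = mean
#'   component intensity, `min_contrast` = `NA`).
#' @export
bpl_detect <- function(image, threshold = 60, min_area = 3, max_area = 200,
                       exclude_on_edges = FALSE, include_holes = FALSE) {
  if (min_area <= 0 || min_area > max_area) {
    stop("need 0 < min_area <= max_area")
  }
  fg <- which(image > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(empty_detections())
  y <- fg[, 1L]; x <- fg[, 2L]
  comp <- pixel_components(x, y)
  if (include_holes) {
    filled <- fill_holes_mask(image > threshold)
    add <- which(filled & !(image > threshold), arr.ind = TRUE)
    if (nrow(add) > 0L) {
      y <- c(y, add[, 1L]); x <- c(x, add[, 2L])
      comp <- pixel_components(x, y)
    }
  }
  out <- lapply(split(seq_along(x), comp), function(i) {
    data.frame(x = mean(x[i]), y = mean(y[i]), scale = 1.0,
               core_mean = mean(image[cbind(y[i], x[i])]),
               min_contrast = NA_real_, area = length(i),
               on_edge = any(y[i] == 1L | y[i] == nrow(image) |
                             x[i] == 1L | x[i] == ncol(image)))
  })
  out <- do.call(rbind, out)
  keep <- out$area >= min_area & out$area <= max_area
  if (exclude_on_edges) keep <- keep & !out$on_edge
  out <- out[keep, c("x", "y", "scale", "core_mean", "min_contrast"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fill holes: background connected (4-conn) to the border stays background,
# enclosed background becomes foreground.
fill_holes_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(mask)
  comp <- pixel_components(bg[, 2L], bg[, 1L])
  border <- bg[, 1L] == 1L | bg[, 1L] == H | bg[, 2L] == 1L | bg[, 2L] == W
  outside <- unique(comp[border])
  hole <- !(comp %in% outside)
  mask[bg[hole, , drop = FALSE]] <- TRUE
  mask
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background by grayscale opening with a
#' ball-shaped structuring element (radius in both the pixel plane and the
#' intensity axis) and subtracts it, clamping to 0-255. No pre-smoothing is
#' applied. Bright features narrower than the ball survive at full contrast;
#' structures wider than the ball diameter are flattened away.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param radius Ball radius in pixels (default 20).
#' @return The background-subtracted image.
#' @export
subtract_background <- function(image, radius = 20) {
  if (radius <= 0) stop("'radius' must be > 0")
  bg <- rolling_ball_background(image, radius)
  pmin(pmax(image - bg, 0), 255)
}

#' Sobel edge enhancement
#'
#' Gradient-magnitude image from the 3x3 Sobel operator (the operation behind
#' ImageJ's "Find Edges"), clamped to 0-255. Border pixels are handled by
#' edge replication.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @return Edge-magnitude image of the same size.
#' @export
find_edges <- function(image) {
  H <- nrow(image); W <- ncol(image)
  pad <- rbind(image[1L, , drop = FALSE], image, image[H, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, W, drop = FALSE])
  sh <- function(dr, dc) pad[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  pmin(sqrt(gx^2 + gy^2), 255)
}

#' Keep only detections brighter than their local periphery
#'
#' Initial filter applied to threshold-based detections: a detection is kept
#' only when the mean intensity inside a disc of radius `annulus_inner`
#' around it exceeds the mean in the annulus `(annulus_inner, annulus_outer]`.
#' Bright particles on darker surroundings pass; dark-centered structures
#' (e.g. hole rims) are removed. Parts of the disc/annulus outside the image
#' are ignored.
#'
#' @param image Image the detections refer to (usually the one that was
#'   labeled, i.e. after any preprocessing).
#' @param detections Detection data frame.
#' @param annulus_inner,annulus_outer Disc and annulus radii in pixels.
#' @return The filtered detection data frame.
#' @export
brighter_than_periphery_filter <- function(image, detections,
                                           annulus_inner = 3, annulus_outer = 8) {
  if (annulus_inner >= annulus_outer) stop("need annulus_inner < annulus_outer")
  if (nrow(detections) == 0L) return(detections)
  r <- ceiling(annulus_outer)
  d <- expand.grid(dr = -r:r, dc = -r:r)
  dist <- sqrt(d$dr^2 + d$dc^2)
  disc <- d[dist <= annulus_inner, ]
  ring <- d[dist > annulus_inner & dist <= annulus_outer, ]
  H <- nrow(image); W <- ncol(image)
  region_mean <- function(cy, cx, off) {
    rr <- round(cy) + off$dr; cc <- round(cx) + off$dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    mean(image[cbind(rr[ok], cc[ok])])
  }
  keep <- vapply(seq_len(nrow(detections)), function(i) {
    region_mean(detections$y[i], detections$x[i], disc) >
      region_mean(detections$y[i], detections$x[i], ring)
  }, logical(1))
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the standard disc template set for multi-template matching
#'
#' Four square templates with centered bright discs: sides 5, 7, 9 and 11
#' pixels, disc diameter `side - 2` at intensity 255, uniform background at
#' levels 55, 60, 65 and 70, with per-template similarity thresholds 0.80,
#' 0.77, 0.74 and 0.70.
#'
#' @return A list of templates, each a list with `side`, `pixels` (matrix),
#'   `similarity_threshold` and `background_level`.
#' @export
mtm_templates <- function() {
  sides <- c(5L, 7L, 9L, 11L)
  thr <- c(0.80, 0.77, 0.74, 0.70)
  bg <- c(55, 60, 65, 70)
  Map(function(s, t, b) {
    h <- (s - 1L) / 2
    d <- outer((-h:h), (-h:h), function(i, j) sqrt(i^2 + j^2))
    px <- matrix(b, s, s)
    px[d <= (s - 2) / 2] <- 255
    list(side = s, pixels = px, similarity_threshold = t, background_level = b)
  }, sides, thr, bg)
}

#' Normalized L1 template similarity at one position
#'
#' The template-matching score: the normalized mean absolute intensity
#' difference between the template and the image window whose top-left pixel
#' is at `(x, y)`,
#' `D = sum(|I - T|) / (255 * w * h)`, returned as `Sim = 1 - D` in `[0, 1]`.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param template A template as produced by [mtm_templates()].
#' @param x,y 1-based column/row of the window's top-left pixel.
#' @return Similarity in `[0, 1]`, or `NA` if the window does not fit.
#' @export
template_similarity <- function(image, template, x, y) {
  s <- template$side
  if (y < 1 || x < 1 || y + s - 1 > nrow(image) || x + s - 1 > ncol(image)) {
    return(NA_real_)
  }
  win <- image[y:(y + s - 1), x:(x + s - 1)]
  1 - sum(abs(win - template$pixels)) / (255 * s * s)
}

# Similarity map for one template at all window centers (vectorized shifts).
# Returns matrix indexed by (center_row - h, center_col - h), h = (side-1)/2.
template_similarity_map <- function(image, template) {
  s <- template$side
  h <- (s - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  nr <- H - 2L * h; nc <- W - 2L * h
  acc <- matrix(0, nr, nc)
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      dr <- i - 1L - h; dc <- j - 1L - h
      acc <- acc + abs(image[(h + 1L + dr):(H - h + dr),
                             (h + 1L + dc):(W - h + dc)] - template$pixels[i, j])
    }
  }
  1 - acc / (255 * s * s)
}

#' Multi-template matching detector
#'
#' Labels positions where the similarity to any template exceeds that
#' template's own threshold. Per-template hits are clustered into detections
#' (8-connected components, centroid position), then the union across
#' templates is deduplicated: detections within `dedup_radius` of a
#' higher-similarity detection are dropped.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param templates List of templates (default [mtm_templates()]).
#' @param dedup_radius Merge radius in pixels (default 4).
#' @return A detection data frame; `core_mean` holds the best similarity (in
#'   0-1), `scale` the template side length used.
#' @export
mtm_detect <- function(image, templates = mtm_templates(), dedup_radius = 4) {
  if (length(templates) == 0L) stop("need at least one template")
  all <- list()
  for (tp in templates) {
    h <- (tp$side - 1L) %/% 2L
    if (nrow(image) < tp$side || ncol(image) < tp$side) next
    sim <- template_similarity_map(image, tp)
    idx <- which(sim > tp$similarity_threshold, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    hits <- data.frame(x = as.numeric(idx[, 2L] + h),
                       y = as.numeric(idx[, 1L] + h),
                       core_mean = sim[idx], min_contrast = sim[idx])
    det <- cluster_hits(hits, scale = tp$side)
    all[[length(all) + 1L]] <- det
  }
  dets <- do.call(rbind, c(all, list(empty_detections())))
  if (nrow(dets) <= 1L) return(dets)
  # keep highest-similarity detection within each dedup neighborhood
  ord <- order(-dets$core_mean)
  keep <- logical(nrow(dets))
  kx <- numeric(0); ky <- numeric(0)
  for (i in ord) {
    if (length(kx) == 0L ||
        min((kx - dets$x[i])^2 + (ky - dets$y[i])^2) > dedup_radius^2) {
      keep[i] <- TRUE
      kx <- c(kx, dets$x[i]); ky <- c(ky, dets$y[i])
    }
  }
  out <- dets[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
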