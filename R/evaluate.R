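# Matching detections to reference annotations and the three benchmark rates.

#' Match detections to reference points
#'
#' One-to-one greedy nearest-first matching: all (detection, reference) pairs
#' with distance <= `tolerance` are sorted by ascending distance (ties broken
#' by detection order, then reference order) and accepted greedily when both
#' members are still unused.
#'
#' @param detections Detection data frame with columns `x`, `y`.
#' @param reference Reference data frame with columns `x`, `y` (optionally
#'   `size`).
#' @param tolerance Maximum match distance in pixels (default 5).
#' @return A list with `pairs` (data frame `det`, `ref`, `dist` of matched
#'   row indices), `unmatched_ref` and `unmatched_det` (integer row indices).
#' @export
match_points <- function(detections, reference, tolerance = 5) {
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  nd <- nrow(detections); nr <- nrow(reference)
  pairs <- data.frame(det = integer(0), ref = integer(0), dist = numeric(0))
  if (nd > 0L && nr > 0L) {
    dx <- outer(detections$x, reference$x, "-")
    dy <- outer(detections$y, reference$y, "-")
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cd <- dist[cand]
      ord <- order(cd, cand[, 1L], cand[, 2L])
      used_d <- logical(nd); used_r <- logical(nr)
      for (k in ord) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!used_d[i] && !used_r[j]) {
          used_d[i] <- TRUE; used_r[j] <- TRUE
          pairs <- rbind(pairs, data.frame(det = i, ref = j, dist = dist[i, j]))
        }
      }
    }
  }
  list(pairs = pairs,
       unmatched_ref = setdiff(seq_len(nr), pairs$ref),
       unmatched_det = setdiff(seq_len(nd), pairs$det))
}

#' Compute detection, false-negative and false-positive rates
#'
#' From the three overlay counts -- matched detections (`n_cyan`), missed
#' references (`n_red`) and spurious detections (`n_green`):
#' \deqn{detection = 100 n_{cyan} / (n_{cyan}+n_{red})}
#' \deqn{FN = 100 n_{red} / (n_{cyan}+n_{red})}
#' \deqn{FP = 100 n_{green} / (n_{cyan}+n_{green})}
#' With no references, detection and FN rates are `NA`; with no detections at
#' all, the FP rate is 0.
#'
#' @param n_cyan,n_red,n_green Non-negative counts.
#' @return A one-row data frame: the three counts plus `detection_rate`,
#'   `false_negative_rate`, `false_positive_rate` (percent).
#' @examples
#' compute_rates(9, 1, 1)  # 90 / 10 / 10
#' @export
compute_rates <- function(n_cyan, n_red, n_green) {
  if (any(c(n_cyan, n_red, n_green) < 0)) stop("counts must be >= 0")
  nref <- n_cyan + n_red
  npos <- n_cyan + n_green
  data.frame(
    n_cyan = n_cyan, n_red = n_red, n_green = n_green,
    detection_rate = if (nref > 0) 100 * n_cyan / nref else NA_real_,
    false_negative_rate = if (nref > 0) 100 * n_red / nref else NA_real_,
    false_positive_rate = if (npos > 0) 100 * n_green / npos else 0
  )
}

#' Evaluate detections against a reference set
#'
#' Convenience wrapper: [match_points()] followed by [compute_rates()].
#'
#' @inheritParams match_points
#' @return As [compute_rates()], with the matching `tolerance` recorded.
#' @export
evaluate_detections <- function(detections, reference, tolerance = 5) {
  m <- match_points(detections, reference, tolerance)
  out <- compute_rates(nrow(m$pairs), length(m$unmatched_ref), length(m$unmatched_det))
  out$tolerance <- tolerance
  out
}

#' Size-stratified detection rates
#'
#' Matching is done globally (one-to-one over all points), then references
#' are partitioned by their annotated size and detection / false-negative
#' rates are computed per bin. The false-positive rate is only meaningful
#' globally (a spurious detection has no reference size) and is therefore
#' reported only in the attached global row (`bin = "all"`).
#'
#' @inheritParams match_points
#' @param size_bins Numeric vector of cut points covering all sizes
#'   (passed to [cut()], right-closed).
#' @return A data frame with one row per bin plus a global `"all"` row.
#' @export
size_stratified_rates <- function(detections, reference, tolerance = 5,
                                  size_bins = c(0, 4, 8, 16)) {
  if (is.null(reference$size) || anyNA(reference$size)) {
    stop("'reference' must carry a complete 'size' column")
  }
  if (min(reference$size) <= min(size_bins) || max(reference$size) > max(size_bins)) {
    stop("'size_bins' must cover all reference sizes")
  }
  m <- match_points(detections, reference, tolerance)
  matched_ref <- m$pairs$ref
  bin <- cut(reference$size, size_bins)
  rows <- lapply(levels(bin), function(b) {
    in_bin <- which(bin == b)
    r <- compute_rates(sum(in_bin %in% matched_ref),
                       sum(!(in_bin %in% matched_ref)), 0)
    r$false_positive_rate <- NA_real_
    cbind(data.frame(bin = b), r)
  })
  glob <- cbind(data.frame(bin = "all"),
                compute_rates(nrow(m$pairs), length(m$unmatched_ref),
                              length(m$unmatched_det)))
  out <- rbind(do.call(rbind, rows), glob)
  rownames(out) <- NULL
  out
}

#' Summarize evaluation results over several images
#'
#' Per-rate arithmetic mean and standard error (sd / sqrt(n)) across images.
#' With a single image the SE is reported as 0 and flagged.
#'
#' @param results A data frame of stacked [compute_rates()] /
#'   [evaluate_detections()] rows (one per image).
#' @return A data frame with one row per rate: `rate`, `mean`, `se`, `n`,
#'   `se_defined`.
#' @export
summarize_images <- function(results) {
  n <- nrow(results)
  if (is.null(n) || n == 0L) stop("need at least one result")
  rates <- c("detection_rate", "false_negative_rate", "false_positive_rate")
  out <- do.call(rbind, lapply(rates, function(r) {
    v <- results[[r]]
    data.frame(rate = r, mean = mean(v),
               se = if (n > 1L) sd(v) / sqrt(n) else 0,
               n = n, se_defined = n > 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Render a color overlay of the evaluation
#'
#' Composites the evaluation onto the grayscale image: cyan dots at matched
#' detections, red dots at missed references (false negatives), light green
#' dots at spurious detections (false positives).
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param detections,reference,tolerance As in [match_points()].
#' @param dot_radius Mark radius in pixels.
#' @return An `H x W x 3` array with values in 0-1 (suitable for
#'   [png::writePNG()]).
#' @export
render_overlay <- function(image, detections, reference, tolerance = 5,
                           dot_radius = 2) {
  m <- match_points(detections, reference, tolerance)
  rgb <- array(rep(image / 255, 3), dim = c(dim(image), 3L))
  draw <- function(xs, ys, col) {
    r <- ceiling(dot_radius)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= dot_radius^2, ]
    for (i in seq_along(xs)) {
      rr <- round(ys[i]) + off$dr; cc <- round(xs[i]) + off$dc
      ok <- rr >= 1L & rr <= nrow(image) & cc >= 1L & cc <= ncol(image)
      for (ch in 1:3) {
        idx <- cbind(rr[ok], cc[ok], ch)
        rgb[idx] <<- col[ch]
      }
    }
  }
  if (nrow(m$pairs) > 0L) {
    draw(detections$x[m$pairs$det], detections$y[m$pairs$det], c(0, 1, 1))      # cyan
  }
  if (length(m$unmatched_ref) > 0L) {
    draw(reference$x[m$unmatched_ref], reference$y[m$unmatched_ref], c(1, 0, 0)) # red
  }
  if (length(m$unmatched_det) > 0L) {
    draw(detections$x[m$unmatched_det], detections$y[m$unmatched_det],
         c(0.56, 0.93, 0.56))                                                    # light green
  }
  rgb
}
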