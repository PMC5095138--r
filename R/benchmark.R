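# Detector dispatch, threshold tuning and the multi-method benchmark.

#' Run a named detector on an image
#'
#' Uniform front end over the five detectors: `"fppl"` (multi-scale
#' flexible-pattern labeling), `"bpl"` (threshold labeling), `"sbp_bpl"`
#' (rolling-ball background subtraction then BPL), `"fep_bpl"` (Sobel edge
#' enhancement then BPL) and `"mtm"` (multi-template matching). The three
#' BPL-family detectors apply the brighter-than-periphery initial filter to
#' their detections, since the targets are brighter than their surroundings.
#'
#' @param image Numeric matrix, intensities 0-255.
#' @param method Detector name.
#' @param config Parameter list from [fppl_config()].
#' @return A detection data frame.
#' @export
detect_particles <- function(image, method = c("fppl", "bpl", "sbp_bpl", "fep_bpl", "mtm"),
                             config = fppl_config()) {
  method <- match.arg(method)
  if (method == "fppl") {
    return(detect_multiscale(image, build_pattern(config$gap_width),
                             th1 = config$th1, th2 = config$th2,
                             scales = config$scales,
                             dedup_radius = config$dedup_radius))
  }
  if (method == "mtm") {
    return(mtm_detect(image, mtm_templates(), dedup_radius = config$dedup_radius))
  }
  work <- switch(method,
    bpl = image,
    sbp_bpl = subtract_background(image, config$rolling_radius),
    fep_bpl = find_edges(image)
  )
  det <- bpl_detect(work, threshold = config$bpl_threshold,
                    min_area = config$min_area, max_area = config$max_area,
                    exclude_on_edges = config$exclude_on_edges,
                    include_holes = config$include_holes)
  brighter_than_periphery_filter(work, det, config$annulus_inner,
                                 config$annulus_outer)
}

#' Tune pattern thresholds by grid search on labeled fixtures
#'
#' Evaluates the multi-scale flexible-pattern detector over a grid of
#' `(th1, th2)` and returns the pair maximizing the mean of
#' `detection_rate - false_positive_rate` across the fixtures. Ties are
#' broken toward the larger `th2`, then the larger `th1` (the more
#' conservative setting). Pattern responses are computed once per fixture
#' and scale and reused across the grid.
#'
#' @param fixtures List of `fppl_fixture` objects.
#' @param th1_grid,th2_grid Candidate threshold values.
#' @param pattern An `fppl_pattern`.
#' @param scales,dedup_radius,tolerance As in [detect_multiscale()] /
#'   [evaluate_detections()].
#' @return A list with `th1`, `th2`, `score` and the full `grid` data frame.
#' @export
tune_thresholds <- function(fixtures,
                            th1_grid = c(60, 80, 100, 120, 140),
                            th2_grid = c(2, 4, 6, 8, 10, 15, 20, 25, 30),
                            pattern = build_pattern(2),
                            scales = c(2, 1, 0.5),
                            dedup_radius = 4, tolerance = 5) {
  # cache responses: one per (fixture, scale)
  cache <- lapply(fixtures, function(fx) {
    lapply(scales, function(s) {
      dims <- round_half_up(dim(fx$image) * s)
      if (any(dims < pattern$side)) return(NULL)
      img <- if (s == 1) fx$image else rescale_image(fx$image, s)
      c(pattern_response(img, pattern), list(scale = s, dim = dim(fx$image)))
    })
  })
  eval_combo <- function(th1, th2) {
    scores <- vapply(seq_along(fixtures), function(i) {
      dets <- lapply(cache[[i]], function(resp) {
        if (is.null(resp)) return(empty_detections())
        hit <- resp$core_mean > th1 & resp$min_contrast > th2
        idx <- which(hit, arr.ind = TRUE)
        hits <- data.frame(x = as.numeric(idx[, 2L] + resp$half),
                           y = as.numeric(idx[, 1L] + resp$half),
                           core_mean = resp$core_mean[idx],
                           min_contrast = resp$min_contrast[idx])
        det <- cluster_hits(hits, scale = resp$scale)
        if (nrow(det) > 0L) {
          det$x <- pmin(pmax((det$x - 0.5) / resp$scale + 0.5, 1), resp$dim[2L])
          det$y <- pmin(pmax((det$y - 0.5) / resp$scale + 0.5, 1), resp$dim[1L])
        }
        det
      })
      det <- dedup_detections(do.call(rbind, c(dets, list(empty_detections()))),
                              dedup_radius)
      r <- evaluate_detections(det, fixtures[[i]]$reference, tolerance)
      r$detection_rate - r$false_positive_rate
    }, numeric(1))
    mean(scores)
  }
  grid <- expand.grid(th1 = th1_grid, th2 = th2_grid)
  grid$score <- mapply(eval_combo, grid$th1, grid$th2)
  best <- grid[order(-grid$score, -grid$th2, -grid$th1), ][1L, ]
  list(th1 = best$th1, th2 = best$th2, score = best$score, grid = grid)
}

#' Benchmark several detectors over several fixtures
#'
#' For each (detector, fixture) pair: detect, evaluate against the fixture's
#' ground truth, record per-image rates; then summarize per detector as mean
#' and standard error across fixtures.
#'
#' @param fixtures List of `fppl_fixture` objects (>= 1).
#' @param methods Character vector of detector names (see
#'   [detect_particles()]).
#' @param config Parameter list from [fppl_config()].
#' @return A list with `per_image` (one row per detector x fixture) and
#'   `summary` (one row per detector x rate: mean, se, n).
#' @export
run_benchmark <- function(fixtures, methods = c("fppl", "bpl", "sbp_bpl", "fep_bpl", "mtm"),
                          config = fppl_config()) {
  if (length(fixtures) == 0L || length(methods) == 0L) {
    stop("need at least one fixture and one method")
  }
  per_image <- NULL
  for (m in methods) {
    for (i in seq_along(fixtures)) {
      det <- detect_particles(fixtures[[i]]$image, m, config)
      r <- evaluate_detections(det, fixtures[[i]]$reference, config$tolerance)
      per_image <- rbind(per_image,
                         cbind(data.frame(method = m, fixture = i), r))
    }
  }
  summary <- NULL
  for (m in methods) {
    s <- summarize_images(per_image[per_image$method == m, , drop = FALSE])
    summary <- rbind(summary, cbind(data.frame(method = m), s))
  }
  rownames(per_image) <- rownames(summary) <- NULL
  list(per_image = per_image, summary = summary)
}
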