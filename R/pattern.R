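#' Build the flexible detection pattern
#'
#' Constructs the square pattern used by the flexible-pattern particle
#' labeling (FpPL) detector: a 3x3 center core `C`, a gap ring `G` of width
#' `gap_width` whose pixels never influence the decision, and eight peripheral
#' blocks `P1..P8` forming the outermost 2-pixel band -- four 2x2 corner
#' blocks and four edge blocks (2x3 on top/bottom, 3x2 on left/right).
#' The pattern side length is `3 + 2 * gap_width + 4`.
#'
#' Peripheral blocks are indexed clockwise from the top-left corner:
#' P1 = top-left corner, P2 = top edge, P3 = top-right corner, P4 = right
#' edge, P5 = bottom-right corner, P6 = bottom edge, P7 = bottom-left corner,
#' P8 = left edge. The conjunction over all eight blocks makes the order
#' immaterial to detection results; it is fixed only for serialization.
#'
#' @param gap_width Integer >= 0, width in pixels of the ignored gap ring
#'   between core and peripheries. The reference configuration is 2
#'   (an 11x11 pattern); 0 and 1 give 7x7 and 9x9 patterns.
#' @return An object of class `fppl_pattern`: a list with `gap_width`,
#'   `side` (side length), `half` ((side-1)/2), `core`, `gap` (integer
#'   matrices of (row, col) offsets relative to the pattern center) and
#'   `periphery` (list of eight offset matrices).
#' @examples
#' p <- build_pattern(2)
#' p$side                       # 11
#' nrow(p$core)                 # 9
#' sum(vapply(p$periphery, nrow, 1L))  # 40
#' @export
build_pattern <- function(gap_width) {
  if (length(gap_width) != 1L || is.na(gap_width) || gap_width < 0 ||
      gap_width != as.integer(gap_width)) {
    stop("'gap_width' must be a single non-negative integer")
  }
  g <- as.integer(gap_width)
  side <- 3L + 2L * g + 4L
  h <- (side - 1L) %/% 2L   # = 3 + g

  offs <- function(rows, cols) {
    as.matrix(expand.grid(dr = as.integer(rows), dc = as.integer(cols)))
  }
  core <- offs(-1:1, -1:1)

  lo <- c(-h, -h + 1L)      # outer band, near side
  hi <- c(h - 1L, h)        # outer band, far side
  periphery <- list(
    P1 = offs(lo, lo),      # top-left corner (2x2)
    P2 = offs(lo, -1:1),    # top edge (2x3)
    P3 = offs(lo, hi),      # top-right corner
    P4 = offs(-1:1, hi),    # right edge (3x2)
    P5 = offs(hi, hi),      # bottom-right corner
    P6 = offs(hi, -1:1),    # bottom edge
    P7 = offs(hi, lo),      # bottom-left corner
    P8 = offs(-1:1, lo)     # left edge
  )

  all_off <- offs(-h:h, -h:h)
  key <- function(m) paste(m[, 1L], m[, 2L])
  used <- c(key(core), unlist(lapply(periphery, key), use.names = FALSE))
  gap <- all_off[!(key(all_off) %in% used), , drop = FALSE]

  structure(
    list(gap_width = g, side = side, half = h,
         core = core, periphery = periphery, gap = gap),
    class = "fppl_pattern"
  )
}

#' @export
print.fppl_pattern <- function(x, ...) {
  cat(sprintf(
    "FpPL pattern: %dx%d (gap width %d)\n  core 3x3 (9 px), periphery 8 blocks (%d px), gap %d px\n",
    x$side, x$side, x$gap_width,
    sum(vapply(x$periphery, nrow, 1L)), nrow(x$gap)))
  invisible(x)
}

#' Format a pattern as a character grid
#'
#' Text rendering of a pattern layout (`C` core, `1`..`8` peripheral blocks,
#' `.` gap), for logging and reproducibility records.
#'
#' @param pattern An `fppl_pattern`.
#' @return Character vector, one element per pattern row.
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "fppl_pattern"))
  h <- pattern$half
  grid <- matrix(".", pattern$side, pattern$side)
  put <- function(m, ch) grid[cbind(m[, 1L] + h + 1L, m[, 2L] + h + 1L)] <<- ch
  put(pattern$core, "C")
  for (i in seq_along(pattern$periphery)) put(pattern$periphery[[i]], as.character(i))
  apply(grid, 1L, paste, collapse = "")
}

#' Evaluate the core-vs-periphery discriminant on one window
#'
#' Decides whether a single square window contains a particle: true iff the
#' core mean exceeds `th1` and the core mean exceeds each of the eight
#' peripheral block means by more than `th2` (strict inequalities). Gap
#' pixels are ignored entirely. Means are floating-point arithmetic means of
#' the raw intensities.
#'
#' @param window Numeric matrix of size `side x side` with intensities 0-255.
#' @param pattern An `fppl_pattern` (see [build_pattern()]).
#' @param th1 Minimum core brightness, 0-255.
#' @param th2 Minimum core-minus-periphery contrast, 0-255.
#' @return Logical scalar.
#' @examples
#' p <- build_pattern(2)
#' w <- matrix(0, 11, 11); w[5:7, 5:7] <- 255
#' evaluate_discriminant(w, p, th1 = 100, th2 = 50)  # TRUE
#' @export
evaluate_discriminant <- function(window, pattern, th1, th2) {
  stopifnot(inherits(pattern, "fppl_pattern"))
  if (!is.matrix(window) || any(dim(window) != pattern$side)) {
    stop(sprintf("'window' must be a %dx%d matrix", pattern$side, pattern$side))
  }
  check_thresholds(th1, th2)
  ctr <- pattern$half + 1L
  block_mean <- function(m) mean(window[cbind(m[, 1L] + ctr, m[, 2L] + ctr)])
  cm <- block_mean(pattern$core)
  if (!(cm > th1)) return(FALSE)
  for (p in pattern$periphery) {
    if (!(cm - block_mean(p) > th2)) return(FALSE)
  }
  TRUE
}

check_thresholds <- function(th1, th2) {
  if (length(th1) != 1L || is.na(th1) || th1 < 0 || th1 > 255) {
    stop("'th1' must be a single value in 0-255")
  }
  if (length(th2) != 1L || is.na(th2) || th2 < 0 || th2 > 255) {
    stop("'th2' must be a single value in 0-255")
  }
  invisible(TRUE)
}
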