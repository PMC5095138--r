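# Synthetic test-image generators with exact ground truth. Every generator
# returns an `fppl_fixture`: the image, the reference point set and a
# provenance record sufficient to regenerate the image bit-exactly.

new_fixture <- function(image, reference, generator, params, seed = NA) {
  structure(
    list(image = image, reference = reference,
         provenance = list(generator = generator, params = params, seed = seed)),
    class = "fppl_fixture"
  )
}

#' @export
print.fppl_fixture <- function(x, ...) {
  cat(sprintf("fppl_fixture '%s': %dx%d image, %d reference points (seed %s)\n",
              x$provenance$generator, nrow(x$image), ncol(x$image),
              nrow(x$reference), format(x$provenance$seed)))
  invisible(x)
}

# Run expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stamp one elliptical dot. `height` is the rendered bounding-box height in
# pixels; width is height * aspect (rounded). Even extents shift the true
# center by half a pixel so the rendered box is symmetric; the returned
# center is the effective one. Profiles:
#   hard    - opaque fill at `peak`
#   soft    - filled ellipse with an anti-aliased ~1 px edge, max-blended
#   plateau - super-Gaussian bright plateau with a soft rim, max-blended
draw_dot <- function(img, x, y, height, aspect = 1, peak = 255,
                     profile = c("hard", "soft", "plateau")) {
  profile <- match.arg(profile)
  w <- max(1L, as.integer(round(height * aspect)))
  cy <- y + if (height %% 2 == 0) 0.5 else 0
  cx <- x + if (w %% 2 == 0) 0.5 else 0
  ry <- height / 2; rx <- w / 2
  r0 <- max(ry, rx) + 2
  rows <- max(1L, floor(cy - r0)):min(nrow(img), ceiling(cy + r0))
  cols <- max(1L, floor(cx - r0)):min(ncol(img), ceiling(cx + r0))
  dy <- (rows - cy) / ry
  dx <- (cols - cx) / rx
  d <- sqrt(outer(dy^2, dx^2, "+"))
  sub <- img[rows, cols, drop = FALSE]
  if (profile == "hard") {
    sub[d <= 1] <- peak
  } else if (profile == "soft") {
    f <- pmin(pmax((1 - d) * min(rx, ry) + 0.5, 0), 1)
    sub <- pmax(sub, (1 - f) * sub + f * peak)
  } else {
    v <- peak * exp(-(d * 1.1)^4)
    sub <- pmax(sub, v)
  }
  img[rows, cols] <- sub
  list(image = img, center = c(x = cx, y = cy))
}

#' Canonical 16-dot variable-size/shape panel
#'
#' A deterministic panel of 16 white (255) dots on black: heights 2, 4, 8 and
#' 16 pixels crossed with aspect ratios 1, 1.5, 2 and 3 (circle to oval), on
#' a 4x4 grid spaced at three times the largest dot width. Used to probe how
#' the pattern's gap width widens the range of detectable sizes and shapes.
#'
#' @return An `fppl_fixture`; the reference carries `size` (dot height) and
#'   `aspect`.
#' @export
make_dot_panel <- function() {
  heights <- c(2, 4, 8, 16)
  aspects <- c(1, 1.5, 2, 3)
  spacing <- 3 * max(heights) * max(aspects)   # 144 px
  margin <- 100
  side <- as.integer(2 * margin + 3 * spacing) # 632
  img <- matrix(0, side, side)
  ref <- NULL
  for (i in seq_along(heights)) {
    for (j in seq_along(aspects)) {
      y <- margin + (i - 1) * spacing
      x <- margin + (j - 1) * spacing
      st <- draw_dot(img, x, y, heights[i], aspects[j], 255, "hard")
      img <- st$image
      ref <- rbind(ref, data.frame(x = st$center[["x"]], y = st$center[["y"]],
                                   size = heights[i], aspect = aspects[j]))
    }
  }
  ref$id <- seq_len(nrow(ref))
  new_fixture(img, ref, "dot_panel",
              list(heights = heights, aspects = aspects, spacing = spacing))
}

# Shared 12x12 dot layout of the two complex-background benchmark images:
# 144 dots, 3 sizes (heights 3/5/9 cycling by row within band), nominal peak
# intensities 145..255 in steps of 10 across columns. On bands whose
# background brightens left to right the intensity ladder ascends with it
# (and descends on darkening bands) so every dot keeps a positive local
# contrast margin.
s2_layout <- function() {
  W <- 480L; H <- 360L
  xs <- 42 + 36 * (0:11)
  bands <- data.frame(top = c(1, 91, 181, 271), bottom = c(90, 180, 270, 360),
                      left = c(255, 43, 232, 0), right = c(0, 232, 43, 255))
  sizes <- c(3, 5, 9)
  dots <- NULL
  for (b in 1:4) {
    ascending <- bands$left[b] < bands$right[b]
    for (r in 1:3) {
      y <- bands$top[b] - 1 + c(15, 45, 75)[r]
      for (j in 1:12) {
        nominal <- if (ascending) 145 + 10 * (j - 1) else 255 - 10 * (j - 1)
        dots <- rbind(dots, data.frame(x = xs[j], y = y, size = sizes[r],
                                       nominal = nominal, band = b))
      }
    }
  }
  list(W = W, H = H, bands = bands, dots = dots)
}

#' Gradient-band benchmark image (144 dots on four gradient bands)
#'
#' Deterministic complex-background test image: four horizontal grayscale
#' gradient bands (white to black, 43 to 232, 232 to 43, black to white) with
#' a 12x12 array of 144 dots of 3 sizes and peak intensities spanning
#' 145-255.
#'
#' @return An `fppl_fixture` with a 480x360 image; reference carries `size`.
#' @export
make_gradient_band_image <- function() {
  lay <- s2_layout()
  img <- matrix(0, lay$H, lay$W)
  for (b in 1:4) {
    g <- lay$bands$left[b] +
      (lay$bands$right[b] - lay$bands$left[b]) * (seq_len(lay$W) - 1) / (lay$W - 1)
    img[lay$bands$top[b]:lay$bands$bottom[b], ] <-
      matrix(round(g), lay$bands$bottom[b] - lay$bands$top[b] + 1, lay$W, byrow = TRUE)
  }
  ref <- NULL
  for (i in seq_len(nrow(lay$dots))) {
    d <- lay$dots[i, ]
    st <- draw_dot(img, d$x, d$y, d$size, 1, d$nominal, "hard")
    img <- st$image
    ref <- rbind(ref, data.frame(x = st$center[["x"]], y = st$center[["y"]],
                                 size = d$size, peak = d$nominal))
  }
  ref$id <- seq_len(nrow(ref))
  new_fixture(img, ref, "gradient_band", list(layout = "s2"))
}

#' Random-block benchmark image (144 dots on random-brightness squares)
#'
#' The same 144-dot layout as [make_gradient_band_image()], but each dot sits
#' centered on a 28x28 square block whose brightness is drawn uniformly from
#' 2-247 with the seeded generator. Each dot is rendered at
#' `max(nominal, min(255, block + 20))`, so every dot stays visibly brighter
#' than its own block (worst-case margin 255 - 247 = 8) while peak
#' intensities remain within 145-255.
#'
#' @param seed Integer seed for the block brightness draw.
#' @return An `fppl_fixture` with a 480x360 image.
#' @export
make_random_block_image <- function(seed) {
  lay <- s2_layout()
  blocks <- with_seed(seed, round(runif(nrow(lay$dots), 2, 247)))
  img <- matrix(0, lay$H, lay$W)
  half <- 14L
  for (i in seq_len(nrow(lay$dots))) {
    d <- lay$dots[i, ]
    rows <- max(1L, d$y - half + 1L):min(lay$H, d$y + half)
    cols <- max(1L, d$x - half + 1L):min(lay$W, d$x + half)
    img[rows, cols] <- blocks[i]
  }
  ref <- NULL
  for (i in seq_len(nrow(lay$dots))) {
    d <- lay$dots[i, ]
    peak <- max(d$nominal, min(255, blocks[i] + 20))
    st <- draw_dot(img, d$x, d$y, d$size, 1, peak, "hard")
    img <- st$image
    ref <- rbind(ref, data.frame(x = st$center[["x"]], y = st$center[["y"]],
                                 size = d$size, peak = peak))
  }
  ref$id <- seq_len(nrow(ref))
  new_fixture(img, ref, "random_block", list(layout = "s2", block_side = 28), seed)
}

# Separable Gaussian blur (truncated at 3 sigma, edge-replicated).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(m) {
    H <- nrow(m)
    acc <- matrix(0, H, ncol(m))
    for (i in -r:r) {
      rows <- pmin(pmax(seq_len(H) + i, 1L), H)
      acc <- acc + k[i + r + 1L] * m[rows, , drop = FALSE]
    }
    acc
  }
  t(blur1(t(blur1(img))))
}

#' SEM-like tissue image with particles, holes and mesh artifacts
#'
#' Emulates a backscattered-electron micrograph of a tissue section: a
#' textured background (smoothed noise around level 40), optional hole-like
#' artifacts (a dark disc with a broad nebulous bright region in its center)
#' and mesh-like artifacts (thin, moderately bright curvilinear strands), and
#' `n_particles` bright particles with a plateau-plus-soft-rim radial
#' profile, seeded sizes (`size_range` pixels in height) and peak intensities
#' (`peak_range`). A fraction of the particles is placed in close pairs, as
#' particles cluster in tissue. Ground truth lists every particle; artifacts
#' are unlabeled (detections there count as false positives).
#'
#' @param n_particles Number of particles (>= 0).
#' @param seed Integer seed.
#' @param holes,mesh Include hole-like / mesh-like artifacts.
#' @param width,height Image size in pixels.
#' @param peak_range,size_range Ranges for particle peak intensity and height.
#' @param clustered_fraction Fraction of particles placed as close pairs.
#' @return An `fppl_fixture`; reference carries `size` and `peak`.
#' @export
make_sem_like_image <- function(n_particles = 30, seed = 1,
                                holes = TRUE, mesh = TRUE,
                                width = 192, height = 192,
                                peak_range = c(130, 255),
                                size_range = c(2, 12),
                                clustered_fraction = 0.2) {
  if (n_particles < 0) stop("'n_particles' must be >= 0")
  with_seed(seed, {
    H <- as.integer(height); W <- as.integer(width)
    tex <- gaussian_blur(matrix(rnorm(H * W), H, W), 2)
    tex <- tex / stats::sd(tex) * 6
    img <- 40 + tex + matrix(rnorm(H * W, sd = 3), H, W)

    # broad, smooth bright ECM regions: tissue matrix in which particles sit
    # "buried"; a global binarization merges anything on them into one huge
    # component, while local-contrast and edge detectors are unaffected
    n_patch <- max(3L, round(H * W / 9000))
    for (k in seq_len(n_patch)) {
      cx <- runif(1, 20, W - 20); cy <- runif(1, 20, H - 20)
      amp <- runif(1, 28, 45); sg <- runif(1, 11, 17)
      d2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")
      img <- img + amp * exp(-d2 / (2 * sg^2))
    }

    if (mesh) {
      n_seg <- max(6L, round(H * W / 3000))
      for (s in seq_len(n_seg)) {
        px <- runif(1, 10, W - 10); py <- runif(1, 10, H - 10)
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 15, 40)
        lift <- runif(1, 11, 16)
        steps <- seq(0, len, by = 0.7)
        for (t in steps) {
          ang <- ang + rnorm(1, sd = 0.15)
          px <- px + 0.7 * cos(ang); py <- py + 0.7 * sin(ang)
          rr <- round(py) + (-1:1); cc <- round(px) + (-1:1)
          ok_r <- rr >= 1 & rr <= H; ok_c <- cc >= 1 & cc <= W
          if (!any(ok_r) || !any(ok_c)) break
          d2 <- outer((rr - py)^2, (cc - px)^2, "+")
          v <- 40 + lift * exp(-d2 / (2 * 0.8^2))
          img[rr[ok_r], cc[ok_c]] <- pmax(img[rr[ok_r], cc[ok_c]],
                                          v[ok_r, ok_c, drop = FALSE])
        }
      }
    }

    hole_centers <- NULL
    if (holes) {
      n_holes <- 2L
      for (k in seq_len(n_holes)) {
        hx <- runif(1, 45, W - 45); hy <- runif(1, 45, H - 45)
        hole_centers <- rbind(hole_centers, c(hx, hy))
        d2 <- outer((seq_len(H) - hy)^2, (seq_len(W) - hx)^2, "+")
        rim <- 1 / (1 + exp((sqrt(d2) - 20) / 2))     # soft dark disc, r ~ 20
        img <- img - 25 * rim
        dome <- 72 * exp(-d2 / (2 * 10^2))            # nebulous bright center
        img <- pmax(img, dome)
      }
    }

    ref <- NULL
    n_pair <- floor(n_particles * clustered_fraction / 2)
    placed <- matrix(numeric(0), ncol = 2)
    margin <- 14
    try_place <- function(min_sep = 14) {
      px <- py <- NA_real_
      for (a in 1:200) {
        px <- runif(1, margin, W - margin); py <- runif(1, margin, H - margin)
        if (nrow(placed) == 0L ||
            min((placed[, 1] - px)^2 + (placed[, 2] - py)^2) > min_sep^2) break
      }
      c(px, py)
    }
    stamp <- function(px, py) {
      # diameters skewed toward small particles, as in SEM micrographs where
      # sub-micron particles dominate the 100 nm - 5 um population
      sz <- round(size_range[1] + (size_range[2] - size_range[1]) * runif(1)^1.7)
      pk <- runif(1, peak_range[1], peak_range[2])
      st <- draw_dot(img, px, py, sz, 1, pk, "plateau")
      img <<- st$image
      placed <<- rbind(placed, c(st$center[["x"]], st$center[["y"]]))
      ref <<- rbind(ref, data.frame(x = st$center[["x"]], y = st$center[["y"]],
                                    size = sz, peak = pk))
    }
    for (k in seq_len(n_pair)) {            # close pairs (clustered particles)
      p <- try_place()
      ang <- runif(1, 0, 2 * pi)
      stamp(p[1], p[2])
      stamp(min(max(p[1] + 7 * cos(ang), margin), W - margin),
            min(max(p[2] + 7 * sin(ang), margin), H - margin))
    }
    for (k in seq_len(n_particles - 2L * n_pair)) {
      p <- try_place()
      stamp(p[1], p[2])
    }
    img <- round(pmin(pmax(img, 0), 255))
    if (is.null(ref)) {
      ref <- data.frame(x = numeric(0), y = numeric(0),
                        size = numeric(0), peak = numeric(0))
    }
    ref$id <- seq_len(nrow(ref))
    fx <- new_fixture(img, ref, "sem_like",
                      list(n_particles = n_particles, holes = holes, mesh = mesh,
                           width = W, height = H, peak_range = peak_range,
                           size_range = size_range,
                           clustered_fraction = clustered_fraction), seed)
    fx$hole_centers <- hole_centers
    fx
  })
}

#' Size-ladder fixture for scale-coverage tests
#'
#' One dot per requested size (hard circles of intensity `peak`) in a row on
#' a clean black background. Optionally adds two large bright non-spherical
#' clutter ellipses (40x24 px, unlabeled) to probe over-shrinking false
#' positives.
#'
#' @param sizes Dot heights in pixels (default 2, 4, 8, 12).
#' @param peak Dot intensity (default 200).
#' @param clutter Add large elliptical clutter (default `FALSE`).
#' @return An `fppl_fixture`; reference carries `size`.
#' @export
make_scale_ladder <- function(sizes = c(2, 4, 8, 12), peak = 200,
                              clutter = FALSE) {
  if (length(sizes) == 0L) stop("'sizes' must be non-empty")
  spacing <- 60; margin <- 40
  W <- as.integer(2 * margin + spacing * (length(sizes) - 1))
  H <- if (clutter) 220L else 80L
  img <- matrix(0, H, W)
  ref <- NULL
  for (i in seq_along(sizes)) {
    st <- draw_dot(img, margin + (i - 1) * spacing, 40, sizes[i], 1, peak, "hard")
    img <- st$image
    ref <- rbind(ref, data.frame(x = st$center[["x"]], y = st$center[["y"]],
                                 size = sizes[i]))
  }
  if (clutter) {
    for (x in c(W * 0.3, W * 0.7)) {
      st <- draw_dot(img, x, 150, 24, 40 / 24, 220, "hard")
      img <- st$image
    }
  }
  ref$id <- seq_len(nrow(ref))
  new_fixture(img, ref, "scale_ladder",
              list(sizes = sizes, peak = peak, clutter = clutter))
}
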