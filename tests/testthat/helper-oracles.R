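# Independent oracles: literal transcriptions of the detector's decision rule
# and the template-matching score, kept free of the package's vectorized
# implementation paths.

# Literal per-window transcription of the two-part decision rule.
discriminant_oracle <- function(window, pattern, th1, th2) {
  ctr <- pattern$half + 1L
  core_vals <- numeric(0)
  for (k in seq_len(nrow(pattern$core))) {
    core_vals <- c(core_vals,
                   window[ctr + pattern$core[k, 1L], ctr + pattern$core[k, 2L]])
  }
  C <- sum(core_vals) / length(core_vals)
  if (!(C > th1)) return(FALSE)
  for (p in pattern$periphery) {
    pv <- numeric(0)
    for (k in seq_len(nrow(p))) {
      pv <- c(pv, window[ctr + p[k, 1L], ctr + p[k, 2L]])
    }
    if (!(C - sum(pv) / length(pv) > th2)) return(FALSE)
  }
  TRUE
}

# Exhaustive per-pixel evaluation over every valid window of an image.
scan_oracle <- function(image, pattern, th1, th2) {
  h <- pattern$half
  hits <- NULL
  for (r in (h + 1L):(nrow(image) - h)) {
    for (c in (h + 1L):(ncol(image) - h)) {
      w <- image[(r - h):(r + h), (c - h):(c + h)]
      if (discriminant_oracle(w, pattern, th1, th2)) {
        hits <- rbind(hits, c(x = c, y = r))
      }
    }
  }
  if (is.null(hits)) data.frame(x = numeric(0), y = numeric(0))
  else as.data.frame(hits)
}

# Literal double-sum transcription of the normalized L1 similarity.
template_sim_oracle <- function(image, template, x, y) {
  s <- template$side
  acc <- 0
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      acc <- acc + abs(image[y + i - 1L, x + j - 1L] - template$pixels[i, j])
    }
  }
  1 - acc / (255 * s * s)
}

random_image <- function(h, w) {
  matrix(round(runif(h * w, 0, 255)), h, w)
}
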