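det_df <- function(x, y) {
  data.frame(x = x, y = y, scale = rep(1, length(x)),
             core_mean = rep(NA_real_, length(x)),
             min_contrast = rep(NA_real_, length(x)))
}

test_that("exact detections match one-to-one with no leftovers", {
  ref <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50))
  m <- match_points(det_df(ref$x, ref$y), ref, 5)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$unmatched_ref, 0L)
  expect_length(m$unmatched_det, 0L)
  # no detections at all
  m0 <- match_points(det_df(numeric(0), numeric(0)),
                     data.frame(x = 1:10, y = 1:10), 5)
  expect_equal(nrow(m0$pairs), 0L)
  expect_length(m0$unmatched_ref, 10L)
})

test_that("equidistant candidates resolve to one match by scan order", {
  ref <- data.frame(x = 20, y = 20)
  det <- det_df(c(18, 22), c(20, 20))   # both at distance 2
  m <- match_points(det, ref, 5)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$det, 1L)          # first detection wins the tie
  expect_equal(m$unmatched_det, 2L)
  # beyond tolerance nothing matches
  expect_equal(nrow(match_points(det, ref, 1)$pairs), 0L)
})

test_that("greedy matching equals optimal assignment cardinality on random cases", {
  set.seed(17)
  for (rep in 1:50) {
    nd <- sample(0:6, 1); nr <- sample(0:6, 1)
    det <- det_df(runif(nd, 0, 40), runif(nd, 0, 40))
    ref <- data.frame(x = runif(nr, 0, 40), y = runif(nr, 0, 40))
    m <- match_points(det, ref, 8)
    # independent oracle: maximum bipartite matching on the tolerance graph
    opt <- 0L
    if (nd > 0 && nr > 0) {
      d <- sqrt(outer(det$x, ref$x, "-")^2 + outer(det$y, ref$y, "-")^2)
      el <- which(d <= 8, arr.ind = TRUE)
      if (nrow(el) > 0) {
        g <- igraph::make_bipartite_graph(
          rep(c(TRUE, FALSE), c(nd, nr)), t(cbind(el[, 1], el[, 2] + nd)))
        opt <- igraph::max_bipartite_match(g)$matching_size
      }
    }
    expect_equal(nrow(m$pairs), opt)
  }
})

test_that("rates follow the three count ratios with exact complementarity", {
  r <- compute_rates(9, 1, 1)
  expect_equal(r$detection_rate, 90)
  expect_equal(r$false_negative_rate, 10)
  expect_equal(r$false_positive_rate, 10)
  expect_equal(compute_rates(0, 10, 0)$detection_rate, 0)
  expect_equal(compute_rates(0, 10, 0)$false_negative_rate, 100)
  expect_equal(compute_rates(144, 0, 0)$detection_rate, 100)
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(0:50, 3, replace = TRUE)
    r <- compute_rates(n[1], n[2], n[3])
    if (n[1] + n[2] > 0) {
      expect_equal(r$detection_rate + r$false_negative_rate, 100)
    } else {
      expect_true(is.na(r$detection_rate))
    }
    expect_true(is.na(r$false_positive_rate) ||
                (r$false_positive_rate >= 0 && r$false_positive_rate <= 100))
  }
  expect_equal(compute_rates(0, 0, 0)$false_positive_rate, 0)
  expect_error(compute_rates(-1, 0, 0), ">= 0")
})

test_that("rates are invariant to input row order", {
  set.seed(29)
  det <- det_df(runif(20, 0, 100), runif(20, 0, 100))
  ref <- data.frame(x = runif(15, 0, 100), y = runif(15, 0, 100))
  a <- evaluate_detections(det, ref, 10)
  b <- evaluate_detections(det[sample(20), ], ref[sample(15), ], 10)
  expect_equal(a$detection_rate, b$detection_rate)
  expect_equal(a$false_positive_rate, b$false_positive_rate)
})

test_that("size-stratified rates partition references but match globally", {
  ref <- data.frame(x = c(10, 30, 50, 70), y = rep(20, 4), size = c(2, 3, 6, 12))
  full <- size_stratified_rates(det_df(ref$x, ref$y), ref, 5, c(0, 4, 8, 16))
  expect_equal(full$detection_rate[full$bin != "all"], c(100, 100, 100))
  # detector that misses the smallest bin only
  part <- size_stratified_rates(det_df(ref$x[3:4], ref$y[3:4]), ref, 5, c(0, 4, 8, 16))
  expect_equal(part$detection_rate[part$bin == "(0,4]"], 0)
  expect_equal(part$detection_rate[part$bin == "(8,16]"], 100)
  expect_equal(part$detection_rate[part$bin == "all"], 50)
  # one bin: per-bin equals global
  one <- size_stratified_rates(det_df(ref$x, ref$y), ref, 5, c(0, 16))
  expect_equal(one$detection_rate[1], one$detection_rate[2])
  expect_error(size_stratified_rates(det_df(1, 1), data.frame(x = 1, y = 1), 5),
               "size")
})

test_that("multi-image summaries report mean and standard error", {
  r <- rbind(compute_rates(8, 2, 0), compute_rates(10, 0, 0))
  s <- summarize_images(r)
  expect_equal(s$mean[s$rate == "detection_rate"], 90)
  expect_equal(s$se[s$rate == "detection_rate"], 10)
  one <- summarize_images(compute_rates(5, 5, 0))
  expect_equal(one$se, rep(0, 3))
  expect_false(any(one$se_defined))
  set.seed(31)
  k <- replicate(8, compute_rates(sample(0:20, 1) + 1, sample(0:20, 1), sample(0:5, 1)),
                 simplify = FALSE)
  k <- do.call(rbind, k)
  s2 <- summarize_images(k)
  expect_equal(s2$mean[1], mean(k$detection_rate))
  expect_equal(s2$se[1], sd(k$detection_rate) / sqrt(8))
  expect_error(summarize_images(k[0, ]), "at least one")
})

test_that("overlays mark matches cyan, misses red and extras light green", {
  img <- matrix(100, 40, 40)
  ref <- data.frame(x = c(10, 20, 30), y = c(10, 10, 10))
  det <- det_df(c(10, 20, 35), c(10, 10, 30))   # 2 matched, 1 FP; ref 3 is FN
  ov <- render_overlay(img, det, ref, tolerance = 3)
  expect_equal(dim(ov), c(40L, 40L, 3L))
  expect_equal(ov[10, 10, ], c(0, 1, 1))          # cyan at matched
  expect_equal(ov[10, 30, ], c(1, 0, 0))          # red at false negative
  expect_equal(ov[30, 35, ], c(0.56, 0.93, 0.56)) # light green at false positive
  # empty evaluation returns the plain grayscale stack
  ov0 <- render_overlay(img, det_df(numeric(0), numeric(0)),
                        data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(ov0[, , 1], img / 255)
  expect_equal(ov0[, , 2], img / 255)
})
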