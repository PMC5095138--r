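test_that("threshold labeling extracts area-filtered component centroids", {
  expect_equal(nrow(bpl_detect(matrix(0, 50, 50))), 0L)
  img <- matrix(0, 50, 50)
  img[10, 10:13] <- 200; img[11, 10] <- 200      # 5-pixel blob
  d <- bpl_detect(img, threshold = 100)
  expect_equal(nrow(d), 1L)
  expect_equal(d$x, mean(c(10, 11, 12, 13, 10)))
  expect_equal(d$y, mean(c(10, 10, 10, 10, 11)))
  # area bounds: a 2-px blob and a 250-px blob both vanish under defaults
  img2 <- matrix(0, 60, 60)
  img2[5, 5:6] <- 200                            # area 2 < 3
  img2[20:44, 20:29] <- 200                      # area 250 > 200
  expect_equal(nrow(bpl_detect(img2, threshold = 100)), 0L)
  expect_error(bpl_detect(img, min_area = 0), "min_area")
})

test_that("edge exclusion and hole filling options behave", {
  img <- matrix(0, 30, 30)
  img[1, 5:8] <- 200                              # touches border
  img[15:19, 15:19] <- 200; img[17, 17] <- 0      # 24 px ring with 1-px hole
  expect_equal(nrow(bpl_detect(img, threshold = 100)), 2L)
  expect_equal(nrow(bpl_detect(img, threshold = 100, exclude_on_edges = TRUE)), 1L)
  d <- bpl_detect(img, threshold = 100, include_holes = TRUE, exclude_on_edges = TRUE)
  expect_equal(nrow(d), 1L)
  expect_equal(d$x, 17)   # filled square centroid
  expect_equal(d$y, 17)
})

test_that("rolling-ball subtraction flattens background but keeps narrow peaks", {
  expect_true(all(subtract_background(matrix(77, 40, 40), 10) == 0))
  # narrow bright dot on a flat field survives at its contrast
  img <- matrix(50, 60, 60); img[30, 30:32] <- 220
  out <- subtract_background(img, 20)
  expect_gt(out[30, 31], 150)
  expect_lt(max(out[1:20, 1:20]), 5)
  # a plateau wider than the ball diameter is substantially flattened
  img2 <- matrix(20, 120, 120); img2[30:90, 30:90] <- 180
  out2 <- subtract_background(img2, 20)
  expect_lt(max(out2), max(img2))
  expect_lt(out2[60, 60], 5)   # plateau interior removed entirely
  expect_error(subtract_background(img2, 0), "radius")
})

test_that("edge enhancement responds to steps and ignores flat regions", {
  expect_true(all(find_edges(matrix(123, 30, 30)) == 0))
  img <- matrix(0, 30, 30); img[, 16:30] <- 200   # vertical step
  e <- find_edges(img)
  expect_equal(dim(e), dim(img))
  expect_gt(e[15, 15], 200)
  expect_equal(e[15, 5], 0)
  expect_lte(max(e), 255)
})

test_that("the brighter-than-periphery filter separates bright dots from dark pits", {
  img <- matrix(100, 80, 160)
  pos <- data.frame(x = c(20, 50, 80, 110, 140, 20, 50, 80, 110, 140),
                    y = c(rep(20, 5), rep(60, 5)))
  for (i in 1:5)  img[pos$y[i] + (-1:1), pos$x[i] + (-1:1)] <- 220   # bright
  for (i in 6:10) img[pos$y[i] + (-1:1), pos$x[i] + (-1:1)] <- 10    # dark
  det <- data.frame(x = pos$x, y = pos$y, scale = 1,
                    core_mean = NA_real_, min_contrast = NA_real_)
  kept <- brighter_than_periphery_filter(img, det)
  expect_equal(nrow(kept), 5L)
  expect_true(all(kept$y == 20))
  expect_error(brighter_than_periphery_filter(img, det, 8, 3), "annulus")
})

test_that("template similarity matches its closed-form transcription", {
  tpl <- mtm_templates()
  expect_equal(vapply(tpl, `[[`, 1L, "side"), c(5L, 7L, 9L, 11L))
  expect_equal(vapply(tpl, `[[`, 1, "similarity_threshold"),
               c(0.80, 0.77, 0.74, 0.70))
  expect_equal(vapply(tpl, `[[`, 1, "background_level"), c(55, 60, 65, 70))
  # self-match and maximal distance
  img <- matrix(0, 30, 30)
  img[10:14, 10:14] <- tpl[[1]]$pixels
  expect_equal(template_similarity(img, tpl[[1]], 10, 10), 1)
  w <- matrix(0, 20, 20)
  t255 <- list(side = 5L, pixels = matrix(255, 5, 5))
  expect_equal(template_similarity(w, t255, 3, 3), 0)
  expect_true(is.na(template_similarity(w, tpl[[1]], 18, 18)))
  # random windows against the literal double sum
  set.seed(13)
  big <- random_image(40, 40)
  for (i in 1:200) {
    tp <- tpl[[sample(4, 1)]]
    x <- sample(40 - tp$side, 1); y <- sample(40 - tp$side, 1)
    expect_equal(template_similarity(big, tp, x, y),
                 template_sim_oracle(big, tp, x, y), tolerance = 1e-12)
  }
})

test_that("template matching detects exact copies and unions over templates", {
  tpl <- mtm_templates()
  expect_equal(nrow(mtm_detect(matrix(0, 60, 60))), 0L)
  img <- matrix(0, 60, 60)
  img[20:24, 30:34] <- tpl[[1]]$pixels
  d <- mtm_detect(img)
  expect_gte(nrow(d), 1L)
  expect_true(any(abs(d$x - 32) <= 2 & abs(d$y - 22) <= 2))
  # lowering a template's similarity threshold can only grow its hit set
  fx <- make_sem_like_image(n_particles = 15, seed = 31, holes = FALSE, mesh = FALSE)
  sim <- fppl:::template_similarity_map(fx$image, tpl[[2]])
  hi <- which(sim > tpl[[2]]$similarity_threshold)
  lo <- which(sim > tpl[[2]]$similarity_threshold - 0.1)
  expect_true(all(hi %in% lo))
  expect_gt(length(lo), length(hi))
  # all four templates find at least as much as any single one
  n_single <- max(vapply(tpl, function(tp) nrow(mtm_detect(fx$image, list(tp))), 1L))
  expect_gte(nrow(mtm_detect(fx$image, tpl)), n_single)
  expect_error(mtm_detect(fx$image, list()), "template")
})
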