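test_that("window CV is the sample sd/mean ratio and is scale invariant", {
  expect_identical(window_cv(c(3, 3, 3)), 0)
  expect_equal(window_cv(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  set.seed(1)
  w <- runif(15, 1, 9)
  expect_equal(window_cv(w * 37.5), window_cv(w), tolerance = 1e-12)
  expect_error(window_cv(5), "at least 2")
})

test_that("stability verdicts honour the CV threshold, boundary inclusive", {
  cfg <- detector_config()
  expect_true(is_stable(rep(4.2, 15), cfg))
  # +/- 6 percent alternation exceeds the 0.05 criterion
  w <- 100 * (1 + 0.06 * (-1)^(1:15))
  expect_gt(window_cv(w), 0.05)
  expect_false(is_stable(w, cfg))
  # boundary: CV exactly at the threshold counts as stable
  cfg2 <- detector_config(cv_threshold = window_cv(w))
  expect_true(is_stable(w, cfg2))
  # everything with a defined CV is stable under a lax threshold
  expect_true(is_stable(w, detector_config(cv_threshold = 0.99)))
  # undefined CV (zero mean) is never stable
  expect_false(is_stable(c(-1, 1, 0), cfg))
})

test_that("dispersed window positions span S to the series end evenly", {
  expect_identical(dispersed_indices(21, 50, 15),
                   c(21L, 23L, 25L, 27L, 29L, 31L, 33L, 36L, 38L, 40L, 42L,
                     44L, 46L, 48L, 50L))
  expect_identical(dispersed_indices(1, 15, 15), 1:15)
  expect_identical(dispersed_indices(1, 29, 15), seq(1L, 29L, 2L))
  expect_null(dispersed_indices(20, 30, 15))
  set.seed(2)
  for (i in 1:50) {
    N <- sample(20:80, 1); K <- sample(3:15, 1)
    S <- sample(seq_len(N - K + 1), 1)
    idx <- dispersed_indices(S, N, K)
    expect_length(idx, K)
    expect_identical(idx[1], as.integer(S))
    expect_identical(idx[K], as.integer(N))
    expect_true(all(diff(idx) >= 1))
  }
})

test_that("stage 1 walks right to left and stops at the first unstable window", {
  cfg <- detector_config()
  expect_null(stage1_backward_search(rep(3, 49), cfg, "consecutive")$roi)

  x <- c(10, rep(1, 29))
  s1 <- stage1_backward_search(x, cfg, "consecutive")
  expect_identical(s1$roi$S, 1L)
  expect_identical(s1$roi$indices, 1:15)
  # every window strictly inside the constant tail was tested and stable
  expect_identical(s1$trace$S, seq(16L, 1L))
  expect_true(all(s1$trace$stable[-16]))

  # worked example: on a 50-value series the S = 21 windows cover 21..35
  # (consecutive) and the dispersed set reaching position 50
  y <- c(rep(c(5, 15), 3), rep(10, 44))
  t1 <- stage1_backward_search(y, cfg, "consecutive")$trace
  row <- t1[t1$S == 21, ]
  expect_identical(c(row$first, row$last), c(21L, 35L))
  t2 <- stage1_backward_search(y, cfg, "dispersed")$trace
  row2 <- t2[t2$S == 21, ]
  expect_identical(c(row2$first, row2$last), c(21L, 50L))

  expect_error(stage1_backward_search(rep(3, 10), cfg), "insufficient data")
})

test_that("stage 2 zooms onto the instability-to-stability transition", {
  cfg <- detector_config()
  # spike at the left edge of the RoI: localization stays beside the spike
  s1 <- stage1_backward_search(c(10, rep(1, 29)), cfg, "consecutive")
  s2 <- stage2_localize(s1$roi, cfg)
  expect_identical(s2$position, 2L)
  expect_identical(nrow(s2$trace), cfg$K - 2L)  # always K-2 iterations

  # spike at the right edge: localization at the RoI's right edge
  s1b <- stage1_backward_search(c(rep(5, 29), 50), cfg, "consecutive")
  s2b <- stage2_localize(s1b$roi, cfg)
  expect_identical(s2b$position, 30L)

  # dispersed RoI results map back through the dispersed index list
  s1c <- stage1_backward_search(c(10, rep(1, 29)), cfg, "dispersed")
  s2c <- stage2_localize(s1c$roi, cfg)
  expect_identical(s2c$position, 3L)
  expect_true(s2c$position %in% s1c$roi$indices)
})

test_that("detect_pos combines both window options by the maximum rule", {
  r <- detect_pos(rep(3, 49), warn = FALSE)
  expect_identical(r$pos, 2)
  expect_identical(unname(r$pos_by_option), c(2, 2))
  expect_true(r$stabilized)

  # frozen oracle values for the left-spike series
  r2 <- detect_pos(c(10, rep(1, 29)), warn = FALSE)
  expect_identical(unname(r2$pos_by_option), c(3, 4))
  expect_identical(r2$pos, 4)

  # an unstable rightmost window flags the trial as not stabilized
  # (both window options warn)
  expect_warning(expect_warning(r3 <- detect_pos(c(rep(5, 29), 50)),
                                "consecutive"), "dispersed")
  expect_false(r3$stabilized)
  expect_identical(r3$pos, 31)

  expect_error(detect_pos(rep(3, 10)), "insufficient data")
})

test_that("noisy-then-constant series are detected near the change stride", {
  set.seed(3)
  for (i in 1:20) {
    x <- noisy_then_constant(15, n = 49, rel_noise = 0.25)
    r <- detect_pos(x, warn = FALSE)
    o <- oracle_detect_pos(x)
    expect_identical(r$pos, o$pos)
    expect_gte(r$pos, 2)
    expect_lte(r$pos, 50)
  }
})

test_that("detector equals the brute-force oracle on heterogeneous series", {
  set.seed(4)
  for (i in 1:60) {
    x <- random_test_series(sample(30:60, 1))
    r <- detect_pos(x, warn = FALSE)
    o <- oracle_detect_pos(x)
    expect_identical(unname(r$pos_by_option), unname(o$pos_by_option))
    expect_identical(r$pos, o$pos)
  }
})

test_that("a stricter CV threshold never moves the stage-1 stop leftward", {
  set.seed(5)
  for (i in 1:20) {
    x <- random_test_series(49)
    S_prev <- NULL
    for (thr in c(0.2, 0.1, 0.05, 0.02)) {
      s1 <- stage1_backward_search(x, detector_config(cv_threshold = thr),
                                   "consecutive")
      S_here <- if (is.null(s1$roi)) 0L else s1$roi$S
      if (!is.null(S_prev)) expect_gte(S_here, S_prev)
      S_prev <- S_here
    }
  }
})

test_that("detection is deterministic, trace included", {
  set.seed(6)
  x <- random_test_series(49)
  expect_identical(detect_pos(x, warn = FALSE), detect_pos(x, warn = FALSE))
})

test_that("block-size sweep tabulates per-K results and flags short series", {
  s <- sweep_block_size(rep(3, 49), K_values = c(5, 10, 15))
  expect_equal(s$pos, rep(2, 3))
  expect_identical(s$note, rep("", 3))

  set.seed(7)
  x <- random_test_series(49)
  s1 <- sweep_block_size(x, 15)
  expect_identical(s1$pos, detect_pos(x, warn = FALSE)$pos)

  s2 <- sweep_block_size(x[1:10], c(5, 15))
  expect_true(is.na(s2$pos[2]))
  expect_match(s2$note[2], "shorter")
  expect_error(sweep_block_size(x, 2), "at least 3")
})
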