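test_that("a constant series yields a single segment", {
  seg <- segment_series(rep(0.4, 400))
  expect_identical(seg$breakpoints, integer(0))
  expect_equal(seg$segment_means, 0.4)
  expect_equal(seg$segment_classes, "intermediate")
})

test_that("a noiseless step is recovered exactly", {
  seg <- segment_series(c(rep(0.2, 200), rep(0.8, 200)))
  expect_equal(seg$breakpoints, 200)
  expect_equal(seg$segment_means, c(0.2, 0.8))
  expect_equal(seg$segment_classes, c("low", "high"))
  expect_equal(seg$rss, 0)
})

test_that("a noisy step is located within 5 observations in 95% of trials", {
  hits <- 0
  set.seed(71)
  for (i in 1:100) {
    y <- c(rep(0.2, 200), rep(0.8, 200)) + rnorm(400, sd = 0.02)
    seg <- segment_series(y)
    hits <- hits +
      (length(seg$breakpoints) == 1 && abs(seg$breakpoints[1] - 200) <= 5)
  }
  expect_gte(hits, 95)
})

test_that("dynamic programming equals exhaustive enumeration", {
  set.seed(72)
  cases <- list(
    c(rep(0.2, 60), rep(0.7, 80), rep(0.85, 60)) + rnorm(200, sd = 0.05),
    c(rep(0.5, 100), rep(0.3, 100)) + rnorm(200, sd = 0.08),
    runif(150, 0.2, 0.8),
    c(seq(0.2, 0.8, length.out = 90), rep(0.8, 90)) + rnorm(180, sd = 0.03)
  )
  for (y in cases) {
    for (m in 1:2) {
      seg <- segment_series(y, n_breaks = m, min_segment_fraction = 0.05)
      h <- max(2L, as.integer(ceiling(0.05 * length(y))))
      oracle <- enum_segment(y, m, h)
      expect_equal(seg$breakpoints, oracle$breaks)
      expect_equal(seg$rss, oracle$rss, tolerance = 1e-10)
    }
  }
})

test_that("segmentation is invariant to adding a constant", {
  set.seed(73)
  y <- c(rep(0.2, 150), rep(0.6, 150)) + rnorm(300, sd = 0.05)
  expect_identical(
    segment_series(y)$breakpoints,
    segment_series(y + 0.17)$breakpoints
  )
})

test_that("short series and infeasible break counts are rejected", {
  expect_error(segment_series(c(0.1, 0.2)), "shorter")
  expect_error(segment_series(rep(0.5, 100), n_breaks = 50), "fit")
  expect_error(segment_series(c(rep(0.2, 50), NA, rep(0.8, 49))), "missing")
})

test_that("first high emergence returns the observations preceding the high segment", {
  seg <- segment_series(c(rep(0.2, 300), rep(0.85, 100)))
  expect_equal(seg$breakpoints, 300)
  expect_equal(first_high_emergence(seg), 300)
  # no high segment
  seg_low <- segment_series(c(rep(0.2, 200), rep(0.5, 200)))
  expect_true(is.na(first_high_emergence(seg_low)))
  # high from the very first segment reports zero experience
  seg_hi <- segment_series(rep(0.81, 400))
  expect_equal(first_high_emergence(seg_hi), 0L)
})

test_that("raising the high threshold never makes emergence earlier", {
  set.seed(74)
  y <- c(rep(0.3, 150), rep(0.78, 100), rep(0.88, 150)) + rnorm(400, sd = 0.02)
  seg <- segment_series(y)
  e1 <- first_high_emergence(seg, high_threshold = 0.7)
  e2 <- first_high_emergence(seg, high_threshold = 0.775)
  e3 <- first_high_emergence(seg, high_threshold = 0.86)
  for (pair in list(c(e1, e2), c(e2, e3))) {
    if (!is.na(pair[1]) && !is.na(pair[2])) expect_lte(pair[1], pair[2])
  }
})

test_that("transition counts respect the differentiation cutoff and classes", {
  steps <- c(rep(0.15, 100), rep(0.85, 100), rep(0.15, 100))
  seg <- segment_series(steps)
  expect_equal(seg$segment_classes, c("low", "high", "low"))
  # both breaks counted
  expect_equal(count_transitions(seg, 0), list(low_to_high = 1L, high_to_low = 1L))
  # cutoff after the first break discards the low-to-high transition
  expect_equal(
    count_transitions(seg, 150),
    list(low_to_high = 0L, high_to_low = 1L)
  )
  expect_equal(
    count_transitions(seg, 1000),
    list(low_to_high = 0L, high_to_low = 0L)
  )
  # intermediate segments count in neither direction
  seg2 <- segment_series(c(rep(0.15, 130), rep(0.5, 140), rep(0.85, 130)))
  expect_equal(seg2$segment_classes, c("low", "intermediate", "high"))
  expect_equal(count_transitions(seg2, 0), list(low_to_high = 0L, high_to_low = 0L))
})
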