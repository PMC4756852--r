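test_that("trace extraction implements the ratio-minus-one normalisation", {
  # uniform stack: damage equals background everywhere
  stack <- array(500, dim = c(16, 16, 4))
  roi <- roi_spec(damage = roi_rect(2, 2, 6, 6),
                  background = roi_rect(8, 8, 14, 14))
  tr <- extract_trace(stack, roi)
  expect_equal(tr$normalized, rep(0, 4))
  # damage exactly 2x background on one frame
  stack[3:6, 3:6, 2] <- 1000
  tr2 <- extract_trace(stack, roi)
  expect_equal(tr2$normalized[2], 1)
  expect_equal(tr2$normalized[c(1, 3, 4)], rep(0, 3))
  # invariance under global multiplicative gain
  tr3 <- extract_trace(stack * 7.3, roi)
  expect_equal(tr3$normalized, tr2$normalized, tolerance = 1e-12)
  # error handling
  expect_error(extract_trace(stack, roi_spec(roi_rect(2, 2, 6, 6),
                                             roi_rect(4, 4, 10, 10))),
               "disjoint")
  expect_error(extract_trace(stack, roi_spec(roi_rect(2, 2, 30, 6),
                                             roi_rect(8, 8, 14, 14))),
               "bounds")
  dark <- array(0, dim = c(16, 16, 3))
  expect_error(extract_trace(dark, roi), "background mean")
})

test_that("noiseless synthetic stacks round-trip through the quantifier", {
  p <- tiny_params()
  r <- render_stack(p)
  tr <- extract_trace(r$stack, default_roi(p), p$frame_times)
  expect_equal(tr$normalized, r$truth$contrast, tolerance = 1e-9)
})

test_that("relative increase recovers the peak-over-baseline ratio", {
  flat <- tibble::tibble(damage_mean = rep(100, 10))
  expect_equal(relative_increase(flat, 3), 0)
  tr <- tibble::tibble(damage_mean = c(100, 100, 150, 120))
  expect_equal(relative_increase(tr, 2), 0.5)
  # synthetic TRF2-like pulse: peak damage_mean = B * (1 + peak contrast)
  p <- tiny_params(kinetics = kinetics_preset("TRF2_high"),
                   frame_times = seq(-0.5, 6, by = 0.1))
  r <- render_stack(p)
  tr2 <- extract_trace(r$stack, default_roi(p), p$frame_times)
  expect_equal(relative_increase(tr2, sum(p$frame_times < 0)),
               max(r$truth$contrast), tolerance = 1e-6)
  expect_error(relative_increase(flat, 0), "pre-damage")
})

test_that("recruitment calling respects the window, level and run length", {
  quiet <- tibble::tibble(time_min = seq(0, 15, 0.5),
                          normalized = rep(0, 31))
  expect_false(call_recruitment(quiet, 15)$recruited)

  p <- tiny_params()
  r <- render_stack(p)
  tr <- extract_trace(r$stack, default_roi(p), p$frame_times)
  call <- call_recruitment(tr, 15, detection_level = 0.1, k = 2)
  expect_true(call$recruited)
  # the preset crosses 0.1 contrast between 5 and 7 min
  expect_gt(call$onset_min, 5)
  expect_lt(call$onset_min, 7)

  # fast transient pulse confined to the first minutes is caught by a 6 min window
  pt <- tiny_params(kinetics = kinetics_preset("TRF2_high"),
                    frame_times = seq(-0.5, 6, by = 0.25))
  rt <- render_stack(pt)
  trt <- extract_trace(rt$stack, default_roi(pt), pt$frame_times)
  ct <- call_recruitment(trt, 6)
  expect_true(ct$recruited)
  expect_lt(ct$peak_min, 1.5)

  # monotone in detection level: raising it never creates a call
  for (lvl in c(0.05, 0.1, 0.3, 0.6, 0.9)) {
    lo <- call_recruitment(tr, 15, lvl)$recruited
    hi <- call_recruitment(tr, 15, lvl + 0.05)$recruited
    expect_false(!lo && hi)
  }
  expect_error(call_recruitment(quiet, -1), "window_min > 0")
})

test_that("threshold power implements the strict majority rule", {
  mk <- function(counts) {
    purrr::map_dfr(names(counts), function(p) {
      tibble::tibble(power = as.numeric(p),
                     recruited = seq_len(8) <= counts[[p]])
    })
  }
  expect_equal(threshold_power(mk(c("20" = 0, "25" = 5, "60" = 8))), 25)
  expect_true(is.na(threshold_power(mk(c("20" = 4))))) # exactly 50% fails
  expect_equal(threshold_power(mk(c("60" = 8))), 60)
  expect_error(threshold_power(data.frame()), "non-empty")
})

test_that("threshold power agrees with a brute-force oracle on random cohorts", {
  set.seed(101)
  for (i in 1:200) {
    powers <- sort(sample(c(20, 25, 60, 85, 100, 125, 155),
                          sample(2:6, 1)))
    calls <- purrr::map_dfr(powers, function(p) {
      n <- sample(3:12, 1)
      tibble::tibble(power = p, recruited = stats::runif(n) < stats::runif(1))
    })
    rule <- sample(c(0.3, 0.5, 0.7), 1)
    expect_identical(threshold_power(calls, rule),
                     brute_force_threshold(calls, rule))
  }
})

test_that("permutation test is calibrated and seeded", {
  same <- c(1.1, 0.9, 1.0, 1.05, 0.95)
  expect_gt(compare_groups(same, same, 2000, seed = 1), 0.9)
  expect_equal(compare_groups(rep(1, 5), rep(1, 5)), 1)
  set.seed(5)
  a <- rnorm(10, 0); b <- rnorm(10, 5)
  expect_lt(compare_groups(a, b, 1e4, seed = 2), 0.01)
  # reproducible given a seed
  expect_identical(compare_groups(a, b, 500, seed = 3),
                   compare_groups(a, b, 500, seed = 3))
  # type-I error near nominal under the null
  set.seed(99)
  rejections <- vapply(1:400, function(i) {
    x <- rnorm(8); y <- rnorm(8)
    compare_groups(x, y, 400) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})
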