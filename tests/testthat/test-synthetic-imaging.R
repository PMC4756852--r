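test_that("kinetic profiles have the stated closed-form behaviour", {
  t <- seq(0, 20, 0.5)
  expect_equal(kinetic_profile(t, "saturating_rise", 0, 1), rep(0, length(t)))
  # value at delay + tau_on is A(1 - 1/e)
  y <- kinetic_profile(c(2, 2 + 3), "saturating_rise", amplitude = 0.5,
                       tau_on = 3, delay = 2)
  expect_equal(y, c(0, 0.5 * (1 - exp(-1))))
  # zero before the delay
  expect_equal(kinetic_profile(c(-1, 0, 0.49), "transient_pulse", 1,
                               0.2, 2, delay = 0.5),
               rep(0, 3))
  expect_error(kinetic_profile(t, "transient_pulse", 1, 2, 1), "exceed")
})

test_that("the 53BP1 preset crosses detection contrast between 5 and 7 min", {
  k <- kinetics_preset("53BP1_low")
  t <- seq(0, 15, by = 0.01)
  y <- kinetic_profile(t, k$model, k$amplitude, k$tau_on, k$tau_off, k$delay)
  crossing <- t[which(y >= 0.1)[1]]
  expect_gt(crossing, 5)
  expect_lt(crossing, 7)
  # sustained: still above detection at the end of the 15 min window
  expect_gt(y[length(y)], 0.1)
})

test_that("the TRF2 preset peaks within 1 min and decays by 5 min", {
  k <- kinetics_preset("TRF2_high")
  t <- seq(0, 6, by = 0.01)
  y <- kinetic_profile(t, k$model, k$amplitude, k$tau_on, k$tau_off, k$delay)
  expect_lt(t[which.max(y)], 1)
  expect_equal(t[which.max(y)],
               pulse_peak_time(k$tau_on, k$tau_off, k$delay),
               tolerance = 0.01)
  expect_lt(y[t == 5], 0.1)
})

test_that("rendering is seed-deterministic and validates geometry", {
  p <- tiny_params(noise = list(poisson_scale = 1, gaussian_sd = 5),
                   seed = 11)
  r1 <- render_stack(p)
  r2 <- render_stack(p)
  expect_identical(r1$stack, r2$stack)
  p2 <- tiny_params(noise = list(poisson_scale = 1, gaussian_sd = 5),
                    seed = 12)
  expect_false(identical(render_stack(p2)$stack, r1$stack))
  # stripe escaping the nucleus is rejected
  expect_error(
    simulation_params(image_shape = c(32, 32),
                      nucleus = list(center = c(16, 16), semi_axes = c(6, 6)),
                      stripe = roi_rect(2, 14, 30, 18)),
    "inside the nucleus")
})

test_that("global photobleaching cancels in the normalised trace", {
  p <- tiny_params(kinetics = kinetics_preset("none"), bleach_rate = 0.1)
  r <- render_stack(p)
  tr <- extract_trace(r$stack, default_roi(p), p$frame_times)
  expect_equal(tr$normalized, rep(0, length(p$frame_times)), tolerance = 1e-9)
  # but the raw damage signal does decay
  expect_lt(tr$damage_mean[length(p$frame_times)], tr$damage_mean[1])
})

test_that("pixel noise variance matches poisson_scale * mean + gaussian_sd^2", {
  p <- simulation_params(
    image_shape = c(24, 24),
    nucleus = list(center = c(12, 12), semi_axes = c(10, 10)),
    stripe = roi_rect(8, 10, 16, 14),
    frame_times = seq(0.5, 150, by = 0.5), # 300 frames
    kinetics = kinetics_preset("none"),
    noise = list(poisson_scale = 1, gaussian_sd = 8),
    seed = 21
  )
  r <- render_stack(p)
  # uniform in-nucleus pixels away from the stripe: averaging the per-pixel
  # variance over the region suppresses single-pixel estimator noise
  region <- r$truth$nucleus_mask & !r$truth$stripe_mask
  region[7:17, ] <- FALSE # guard band around the stripe rows
  vals <- apply(r$stack, 3, function(f) f[region])
  per_pixel_var <- apply(vals, 1, var)
  expected <- 1 * 1000 + 8^2
  expect_equal(mean(per_pixel_var), expected, tolerance = 0.05)
  expect_equal(mean(vals), 1000, tolerance = 0.01)
})

test_that("cohort simulation is reproducible and carries ground truth", {
  sampler <- function(i) tiny_params(noise = list(poisson_scale = 1,
                                                  gaussian_sd = 5))
  c1 <- simulate_cohort(3, sampler, seed = 7)
  c2 <- simulate_cohort(3, sampler, seed = 7)
  expect_identical(c1$stack, c2$stack)
  expect_equal(nrow(c1), 3)
  expect_false(identical(c1$stack[[1]], c1$stack[[2]]))
  expect_s3_class(c1$truth[[1]]$params, "simulation_params")
  single <- simulate_cohort(1, sampler, seed = 9)
  expect_equal(nrow(single), 1)
})

test_that("mixed responder cohorts yield the constructed recruited fraction", {
  sampler <- function(i) {
    k <- if (i <= 5) kinetics_preset("53BP1_low") else kinetics_preset("none")
    tiny_params(kinetics = k, noise = list(poisson_scale = 1, gaussian_sd = 5))
  }
  cohort <- simulate_cohort(8, sampler, seed = 31)
  calls <- purrr::map2_lgl(cohort$stack, cohort$truth, function(st, tr) {
    trace <- extract_trace(st, default_roi(tr$params), tr$params$frame_times)
    call_recruitment(trace, 15)$recruited
  })
  expect_equal(mean(calls), 5 / 8)
})
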