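test_that("steady-state detection recovers plateaus and rejects ramps", {
  const <- make_trace(seq(-15, 40), rep(0.2, 56))
  ss <- detect_steady_state(const, "pre")
  expect_equal(ss$level, 0.2)
  expect_equal(ss$residual_slope, 0)

  ramp <- make_trace(seq(-15, 40), 0.1 + 0.005 * (seq(-15, 40) + 15))
  expect_error(detect_steady_state(ramp, "pre", slope_tol = 0.001),
               class = "stomavpd_no_steady_state")

  # noisy plateau: level within the 3-sigma sampling-theory bound of truth
  noisy <- withr::with_seed(101, make_trace(seq(-15, 40),
                                            0.15 + stats::rnorm(56, 0, 0.002)))
  ss_n <- detect_steady_state(noisy, "pre", plateau_window_min = 10)
  expect_lt(abs(ss_n$level - 0.15), 3 * 0.002 / sqrt(10))
})

test_that("latest qualifying window wins on a settle-then-plateau trace", {
  t <- seq(-15, 45)
  g <- ifelse(t < 0, 0.2, 0.12 + 0.08 * exp(-t / 5))
  tr <- apply_artifact_mask(make_trace(t, g), mask_min = 3)
  ss <- detect_steady_state(tr, "post")
  expect_equal(ss$window[2], 45)   # ends at the last record
  expect_gt(ss$window[1], 20)      # not an early, still-relaxing window
})

test_that("amplitude is peak minus baseline inside the search window", {
  # plateau 0.20, masked artifact minutes, then peak 0.25 at t=5, decay below
  post <- c(0.9, 0.9, 0.9, 0.23, 0.24, 0.25, 0.24, 0.22, 0.21, 0.205, 0.19,
            rep(0.18, 30))
  tr <- apply_artifact_mask(make_step_fixture(0.20, post), mask_min = 3)
  amp <- wwr_amplitude(tr, 0.20)
  expect_equal(amp$amplitude, 0.05)
  expect_equal(amp$peak_time_min, 5)
  expect_length(amp$flags, 0)
})

test_that("a peak hidden inside the mask yields a flagged non-positive amplitude", {
  post <- c(0.30, 0.28, 0.25, 0.19, 0.18, rep(0.17, 36))
  tr <- apply_artifact_mask(make_step_fixture(0.20, post), mask_min = 3)
  amp <- wwr_amplitude(tr, 0.20)
  expect_lte(amp$amplitude, 0)
  expect_true("no_resolvable_overshoot" %in% amp$flags)
})

test_that("late noise excursions beyond the first crossing never set the peak", {
  post <- c(0.5, 0.5, 0.5, 0.22, 0.21, 0.19, 0.18, rep(0.17, 20), 0.26,
            rep(0.17, 15))
  tr <- apply_artifact_mask(make_step_fixture(0.20, post), mask_min = 3)
  amp <- wwr_amplitude(tr, 0.20)
  expect_equal(amp$amplitude, 0.02)   # 0.22 at t=3, not 0.26 at t=27
})

test_that("duration criterion A interpolates the baseline crossing", {
  # symmetric straddle: 0.21 at t=11, 0.19 at t=13 (gap at t=12), g_t0 = 0.20
  t <- c(seq(-15, 10), 11, 13, seq(14, 40))
  g <- c(rep(0.20, 15), 0.5, 0.5, 0.5, 0.27, 0.26, 0.25, 0.24, 0.23, 0.225,
         0.22, 0.215, 0.21, 0.19, c(0.17, rep(0.15, 26)))
  tr <- apply_artifact_mask(make_trace(t, g), mask_min = 3)
  ss_pre <- detect_steady_state(tr, "pre")
  ss_post <- detect_steady_state(tr, "post")
  dur <- wwr_duration(tr, ss_pre, ss_post, equality_band = 0.004)
  expect_equal(dur$criterion, "return_to_baseline")
  expect_equal(dur$duration_min, 12)  # linear interpolation between 11 and 13
})

test_that("duration criterion B is the settling time into the new higher level", {
  post <- c(0.5, 0.5, 0.5, 0.40, 0.37, 0.34, 0.31, 0.295, 0.28, 0.272, 0.265,
            0.258, 0.252, 0.248, 0.245, c(0.241, rep(0.24, 25)))
  tr <- apply_artifact_mask(make_step_fixture(0.20, post), mask_min = 3)
  ss_pre <- detect_steady_state(tr, "pre")
  ss_post <- detect_steady_state(tr, "post")
  expect_gt(ss_post$level, 0.2)
  dur <- wwr_duration(tr, ss_pre, ss_post, equality_band = 0.004)
  expect_equal(dur$criterion, "reach_new_steady_state")
  expect_equal(dur$duration_min, 15)  # first in-band minute that persists
})

test_that("a constant trace is degenerate with zero duration", {
  tr <- apply_artifact_mask(make_trace(seq(-15, 40), rep(0.2, 56)), mask_min = 3)
  ss <- detect_steady_state(tr, "pre")
  ss_post <- detect_steady_state(tr, "post")
  dur <- wwr_duration(tr, ss, ss_post, equality_band = 0.004)
  expect_equal(dur$criterion, "degenerate")
  expect_equal(dur$duration_min, 0)
})

test_that("criterion A errors when baseline is never re-attained", {
  post <- c(0.5, 0.5, 0.5, 0.30, 0.28, 0.26, 0.25, rep(0.24, 34))
  tr <- apply_artifact_mask(make_step_fixture(0.20, post), mask_min = 3)
  ss_pre <- detect_steady_state(tr, "pre")
  ss_post <- detect_steady_state(tr, "post")
  fake_low <- ss_post
  fake_low$level <- 0.10   # force criterion A on a trace that never crosses
  expect_error(wwr_duration(tr, ss_pre, fake_low, equality_band = 0.004),
               class = "stomavpd_no_crossing")
})

test_that("cumulative water loss integrates E over [mask, duration)", {
  tr <- apply_artifact_mask(
    make_step_fixture(0.20, c(0.5, 0.5, 0.5, rep(0.22, 38)),
                      e_trans_const = 0.005),
    mask_min = 3)
  # 7 one-minute intervals from t=3 to t=10 at E = 0.005: 0.005 * 60 * 7
  loss <- cumulative_wwr_water_loss(tr, duration_min = 10, mask_min = 3)
  expect_equal(loss$cumulative_water_loss, 2.1)

  zero <- tr
  zero$e_trans <- 0
  expect_equal(cumulative_wwr_water_loss(zero, 10, 3)$cumulative_water_loss, 0)

  expect_warning(short <- cumulative_wwr_water_loss(tr, duration_min = 2, mask_min = 3),
                 "inside the artifact mask")
  expect_equal(short$cumulative_water_loss, 0)
  expect_true("duration_inside_mask" %in% short$flags)
})

test_that("cumulative loss is monotone in duration and refinement-stable", {
  p <- trace_params(noise_sd = 0)
  tr <- apply_artifact_mask(simulate_trace(p), mask_min = 3)
  durations <- seq(4, 20, by = 2)
  losses <- vapply(durations, function(d) {
    cumulative_wwr_water_loss(tr, d, 3)$cumulative_water_loss
  }, numeric(1))
  expect_true(all(diff(losses) >= 0))

  # halving the sampling interval on the same smooth curve changes the sum < 2%
  p_fine <- trace_params(noise_sd = 0, sampling_interval = 0.5)
  tr_fine <- apply_artifact_mask(simulate_trace(p_fine), mask_min = 3)
  d <- 12
  coarse <- cumulative_wwr_water_loss(tr, d, 3)$cumulative_water_loss
  fine <- cumulative_wwr_water_loss(tr_fine, d, 3)$cumulative_water_loss
  expect_lt(abs(fine - coarse) / coarse, 0.02)
})

test_that("steady-state delta signs closure and labels hyposensitivity", {
  expect_equal(steady_state_delta(0.20, 0.12)$delta_gss, 0.08)
  expect_equal(steady_state_delta(0.20, 0.22)$delta_gss, -0.02)
  eq <- steady_state_delta(0.20, 0.20, equality_band = 0.004)
  expect_equal(eq$delta_gss, 0)
  expect_true(eq$hyposensitive)
  expect_false(steady_state_delta(0.20, 0.12, 0.004)$hyposensitive)
})

test_that("extraction is deterministic and composes all stages", {
  tr <- simulate_trace(trace_params(seed = 77))
  m1 <- extract_wwr(tr)
  m2 <- extract_wwr(tr)
  expect_identical(m1, m2)   # bit-identical on identical trace + config
  td <- tidy(m1)
  expect_equal(nrow(td), 1)
  expect_true(all(c("amplitude", "duration_min", "cumulative_water_loss",
                    "delta_gss", "duration_criterion", "g_t0") %in% names(td)))
  expect_gte(m1$cumulative_water_loss, 0)
  expect_gte(m1$duration_min, 0)
})

test_that("extraction rejects traces that are too short and names failing stages", {
  short <- make_trace(seq(-2, 12), rep(0.2, 15))
  expect_error(extract_wwr(short), "too short")
  ramp <- make_trace(seq(-15, 45), 0.1 + 0.004 * seq(0, 60))
  expect_error(extract_wwr(ramp), "detect_steady_state")
})

test_that("parameter recovery under noise stays within the sampling-theory bounds", {
  # separable pulse (no closure component): amplitude error is pure noise error
  n_rep <- 60
  p0 <- trace_params(g_new = 0.20, A = 0.05, tau_rise = 4, noise_sd = 0.005)
  errs <- vapply(seq_len(n_rep), function(i) {
    p <- p0; p$seed <- 3000 + i
    m <- extract_wwr(simulate_trace(p))
    c(abs(m$amplitude - 0.05), abs(m$delta_gss - 0))
  }, numeric(2))
  expect_lte(stats::median(errs[1, ]), 2 * 0.005)
  expect_lte(stats::median(errs[2, ]), 2 * 0.005 / sqrt(10))
})
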