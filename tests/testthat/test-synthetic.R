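test_that("all components off yields a constant trace at g0", {
  p <- trace_params(g_new = 0.20, A = 0, artifact_height = 0, noise_sd = 0)
  tr <- simulate_trace(p)
  expect_true(all(tr$gsw == 0.20))
  expect_equal(tr$e_trans, tr$gsw * tr$vpd_kpa / 101.3)
})

test_that("the overshoot pulse attains its maximum A exactly at t = tau_rise", {
  p <- trace_params(g_new = 0.20, A = 0.08, tau_rise = 4, artifact_height = 0,
                    noise_sd = 0, sampling_interval = 0.01)
  tr <- simulate_trace(p)
  excess <- tr$gsw - 0.20
  k <- which.max(excess)
  expect_equal(excess[k], 0.08, tolerance = 1e-6)
  expect_equal(tr$time_min[k], 4, tolerance = 0.011)
})

test_that("seeding makes traces reproducible and distinguishable", {
  a <- simulate_trace(trace_params(seed = 123))
  b <- simulate_trace(trace_params(seed = 123))
  c <- simulate_trace(trace_params(seed = 124))
  expect_identical(a$gsw, b$gsw)
  expect_gt(max(abs(a$gsw - c$gsw)), 1e-4)
  # serialized round trip is byte-identical under the same seed
  fa <- tempfile(); fb <- tempfile()
  write_trace(a, fa); write_trace(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("simulation leaves the caller's RNG stream untouched when seeded", {
  withr::with_seed(1, {
    before <- .Random.seed
    invisible(simulate_trace(trace_params(seed = 99)))
    expect_identical(.Random.seed, before)
  })
})

test_that("panels are counted, labelled, and seeded deterministically", {
  pan <- simulate_panel(c("wildtype", "reduced_wwr"), 3, seed = 42)
  expect_equal(nrow(pan), 6)
  expect_equal(sort(unique(pan$archetype)), c("reduced_wwr", "wildtype"))
  genos <- vapply(pan$trace, attr, character(1), "genotype")
  expect_identical(unname(genos), pan$archetype)
  pan2 <- simulate_panel(c("wildtype", "reduced_wwr"), 3, seed = 42)
  expect_identical(pan$seed, pan2$seed)
  expect_identical(pan$trace[[1]]$gsw, pan2$trace[[1]]$gsw)
  expect_error(simulate_panel("no_such_type", 3, seed = 1), "Unknown archetype")
  expect_error(simulate_panel("wildtype", 1, seed = 1), ">= 2")
})

test_that("archetypes express their defining phenotypes at zero noise", {
  base <- trace_params(noise_sd = 0)
  m_wt <- extract_wwr(simulate_trace(archetype_params("wildtype", base)))
  m_hypo <- extract_wwr(simulate_trace(archetype_params("hyposensitive_steady_state", base)))
  m_slow <- extract_wwr(simulate_trace(archetype_params("slow_kinetics", base)))
  m_red <- extract_wwr(simulate_trace(archetype_params("reduced_wwr", base)))

  expect_gt(m_wt$delta_gss, m_wt$equality_band)          # closure below baseline
  expect_lte(abs(m_hypo$delta_gss), m_hypo$equality_band) # no steady-state change
  expect_true(m_hypo$hyposensitive_steady_state)
  expect_gt(m_slow$duration_min, m_wt$duration_min)      # slower kinetics
  expect_lt(m_red$amplitude, m_wt$amplitude)             # smaller overshoot
})

test_that("artificial leaves read constant once the artifact window is excluded", {
  tr0 <- simulate_artificial_leaf(0.15, artifact_height = 0.08, noise_sd = 0)
  masked <- apply_artifact_mask(tr0, mask_min = 3)
  keep <- !masked$masked
  expect_true(all(masked$gsw[keep] == 0.15))   # exact: artifact confined to t < 3

  m <- extract_wwr(tr0)
  expect_lte(abs(m$delta_gss), m$equality_band)
  expect_equal(m$duration_min, 0)
  expect_true("no_resolvable_overshoot" %in% m$flags)

  # doubling the artifact cannot change any masked metric
  tr2 <- simulate_artificial_leaf(0.15, artifact_height = 0.16, noise_sd = 0)
  expect_identical(glance(extract_wwr(tr2)), glance(m))
})

test_that("spread of the steady-state delta scales with the plateau sampling error", {
  noise_sd <- 0.005
  n_window <- 11   # samples in a 10-min plateau window at 1-min logging
  deltas <- vapply(seq_len(400), function(i) {
    p <- trace_params(noise_sd = noise_sd, seed = 20000 + i)
    extract_wwr(simulate_trace(p))$delta_gss
  }, numeric(1))
  ratio <- sd(deltas) / (noise_sd / sqrt(n_window))
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("parameter constructors reject invalid values before sampling", {
  expect_error(trace_params(g0 = -0.1), "non-negative")
  expect_error(trace_params(tau_rise = 0), "positive")
  expect_error(trace_params(noise_sd = -1), "non-negative")
  expect_error(trace_params(sampling_interval = 0), "positive")
  expect_error(simulate_artificial_leaf(0), "positive")
  expect_error(archetype_params("imaginary"), "Unknown archetype")
})
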