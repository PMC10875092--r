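test_that("Welch t and p match the closed-form oracle to 1e-10", {
  withr::with_seed(7, {
    for (i in seq_len(100)) {
      nx <- sample(3:8, 1); ny <- sample(3:8, 1)
      x <- stats::rnorm(nx, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.2, 2))
      y <- stats::rnorm(ny, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.2, 2))
      res <- compare_metric(x, y, "m")
      orc <- oracle_welch(y, x)   # geno - ref ordering
      expect_lt(abs(res$t_stat - orc$t), 1e-10)
      expect_lt(abs(res$p_value - orc$p), 1e-10)
      expect_lt(abs(res$df - orc$df), 1e-10)
    }
  })
})

test_that("degenerate and shifted samples behave as the t-test demands", {
  same <- compare_metric(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  shifted <- compare_metric(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.05)

  expect_error(compare_metric(rep(0, 4), rep(1, 4)), "zero variance")
  expect_error(compare_metric(1, c(1, 2)), "n >= 2")
  expect_error(compare_metric(c(1, 2), c(1, NA)), "finite")
})

test_that("significance stars follow the printed caption coding, boundaries included", {
  p <- c(0.2, 0.05, 0.049999, 0.010001, 0.01, 0.0099, 0.00011, 1e-4, 9.9e-5, 0)
  expect_identical(
    stars_from_p(p),
    c("ns", "ns", "*", "*", "*", "**", "**", "**", "***", "***")
  )
  # the *** cutpoint is 1e-4 as printed, not the conventional 1e-3
  expect_identical(stars_from_p(5e-4), "**")
  expect_identical(stars_from_p(5e-4, thresholds = c(0.05, 0.01, 0.001)), "***")
  expect_error(stars_from_p(1.2), "\\[0, 1\\]")
})

test_that("compare_wwr tests every genotype and metric against the reference", {
  pan <- simulate_panel(c("wildtype", "hyposensitive_steady_state", "reduced_wwr"),
                        4, seed = 31)
  metrics <- purrr::map_dfr(pan$trace, ~ tidy(extract_wwr(.x)))
  cmp <- compare_wwr(metrics, reference = "wildtype")
  expect_equal(nrow(cmp), 2 * 4)   # 2 non-reference genotypes x 4 metrics
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$stars %in% c("ns", "*", "**", "***")))
  # a hyposensitive line differs from wildtype in steady-state delta
  row <- cmp[cmp$genotype == "hyposensitive_steady_state" &
               cmp$metric_name == "delta_gss", ]
  expect_lt(row$p_value, 0.05)
  expect_error(compare_wwr(metrics, reference = "absent"), "not present")
})

test_that("percent change applies the strict <75% hyposensitivity rule", {
  res <- screen_percent_change(tibble::tibble(
    cultivar = c("a", "b", "c"),
    g_before = c(0.5, 0.4, 0.4),
    g_after = c(0.2, 0.0, 0.1)
  ))
  expect_equal(res$pct_change, c(60, 100, 75))
  expect_identical(res$sensitivity_class, c("hyposensitive", "sensitive", "sensitive"))
  expect_error(screen_percent_change(tibble::tibble(
    cultivar = "x", g_before = 0, g_after = 0)), "positive")
})

test_that("percent change is invariant to rescaling both conductances", {
  base <- tibble::tibble(cultivar = "x", g_before = 0.37, g_after = 0.11)
  for (c_scale in c(0.5, 2, 10)) {
    scaled <- dplyr::mutate(base, g_before = g_before * c_scale,
                            g_after = g_after * c_scale)
    expect_equal(screen_percent_change(scaled)$pct_change,
                 screen_percent_change(base)$pct_change)
  }
})

test_that("replicate aggregation is per-plant-first with SEM over plants", {
  readings <- tidyr::expand_grid(
    cultivar = "cv1", phase = "before", plant = c("p1", "p2"), rep = 1:8
  )
  readings$reading <- ifelse(readings$plant == "p1", 0.3, 0.5)
  agg <- aggregate_replicates(readings, k_expected = 8)
  expect_equal(agg$mean, 0.4)             # mean of plant means
  expect_equal(agg$n_plants, 2)           # n counts plants, not readings
  expect_equal(agg$sem, sd(c(0.3, 0.5)) / sqrt(2))

  single <- tibble::tibble(cultivar = "cv1", phase = "before", plant = "p1",
                           reading = rep(0.42, 8))
  agg1 <- aggregate_replicates(single, k_expected = 8)
  expect_equal(agg1$mean, 0.42)

  expect_warning(aggregate_replicates(single[1:5, ], k_expected = 8), "k_expected")
  expect_error(aggregate_replicates(single[0, ]), "empty")
})

test_that("run_screen composes aggregation, reshaping and classification", {
  readings <- tidyr::expand_grid(
    cultivar = c("sens", "hypo"), phase = c("before", "after"),
    plant = paste0("p", 1:4), rep = 1:8
  )
  readings$reading <- dplyr::case_when(
    readings$phase == "before" ~ 0.40,
    readings$cultivar == "sens" ~ 0.04,   # 90% reduction
    .default = 0.20                        # 50% reduction
  )
  out <- run_screen(readings)
  expect_equal(nrow(out), 2)
  expect_identical(out$sensitivity_class[out$cultivar == "sens"], "sensitive")
  expect_identical(out$sensitivity_class[out$cultivar == "hypo"], "hyposensitive")
  expect_equal(out$pct_change[out$cultivar == "sens"], 90)
})
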