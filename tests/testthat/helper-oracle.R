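# Independent oracles: brute-force/closed-form reference computations that
# never call the package's extraction path.

# Continuous three-component curve, written out directly from the generative
# definition (baseline for t < 0; relaxation + normalized pulse + confined
# artifact for t >= 0).
oracle_curve <- function(t, p, with_artifact = TRUE) {
  out <- numeric(length(t))
  pre <- t < 0
  out[pre] <- p$g0
  tp <- t[!pre]
  g <- p$g_new + (p$g0 - p$g_new) * exp(-tp / p$tau_close) +
    p$A * (tp / p$tau_rise) * exp(1 - tp / p$tau_rise)
  if (with_artifact) {
    g <- g + ifelse(tp < 3, p$artifact_height * exp(-tp / p$artifact_decay), 0)
  }
  out[!pre] <- g
  out
}

# Dense-grid brute force over the post-step curve: first baseline crossing
# from above, and the peak inside (mask, min(search_max, crossing)).
oracle_wwr <- function(p, mask_min = 3, search_max = 20, t_end = p$duration_total,
                       dt = 0.001) {
  t <- seq(0, t_end, by = dt)
  g <- oracle_curve(t, p, with_artifact = FALSE)
  above <- g > p$g0
  # first downward crossing after the curve has been above baseline
  cross_idx <- which(above[-length(above)] & !above[-1])
  crossing <- if (length(cross_idx)) t[cross_idx[1] + 1] else NA_real_
  upper <- min(search_max, if (is.na(crossing)) Inf else crossing)
  sel <- t >= mask_min & t <= upper
  if (!any(sel)) sel <- t >= mask_min
  k <- which.max(g[sel])
  list(
    peak_time = t[sel][k],
    amplitude = g[sel][k] - p$g0,
    crossing = crossing,
    # largest change of the curve across one coarse sampling interval,
    # i.e. the worst-case discretization error of a per-interval grid
    max_step_change = max(abs(
      oracle_curve(t + p$sampling_interval, p, with_artifact = FALSE) - g
    ))
  )
}

# Window mean of the noiseless curve -- the truth an extracted plateau level
# is compared against, on the same per-minute grid the extractor saw.
oracle_window_mean <- function(p, window, dt = p$sampling_interval) {
  t <- seq(window[1], window[2], by = dt)
  mean(oracle_curve(t, p, with_artifact = FALSE))
}

# Welch two-sample t-test from the closed-form expressions.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}
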