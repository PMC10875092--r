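#' Detect a steady-state plateau
#'
#' Scans sliding windows of length `plateau_window_min` over the unmasked
#' records on one side of the step and returns the *latest* window whose
#' least-squares slope magnitude is at most `slope_tol` and whose coefficient
#' of variation is at most `cv_tol`. The plateau level is the window mean.
#'
#' Steady state is an operational notion here: conductance typically needs
#' 20-30 minutes to establish a plateau, and the latest qualifying window is
#' taken so that slow relaxation tails bias the level as little as possible.
#'
#' @param trace A [gx_trace()] (mask applied for the post side).
#' @param side `"pre"` (records before the step) or `"post"` (unmasked
#'   records at or after `masked_until_min`).
#' @param plateau_window_min Window length, minutes.
#' @param slope_tol Max |OLS slope|, mol m^-2 s^-1 per minute.
#' @param cv_tol Max coefficient of variation (sd/mean) of the window.
#' @return A `steady_state`: list with `level`, `window = c(start, end)` in
#'   minutes, `residual_slope`, `sd`, `se`, `cv`, `n`.
#' @examples
#' tr <- gx_trace(tibble::tibble(time_min = -15:40, gsw = 0.2))
#' detect_steady_state(tr, "pre")
#' @export
detect_steady_state <- function(trace, side = c("pre", "post"),
                                plateau_window_min = 10,
                                slope_tol = 0.001, cv_tol = 0.05) {
  side <- match.arg(side)
  stopifnot(inherits(trace, "gx_trace"))
  rec <- unmasked(trace)
  rec <- if (side == "pre") rec[rec$time_min < 0, ] else rec[rec$time_min >= 0, ]
  if (nrow(rec) < 3) {
    abort(sprintf("Too few unmasked records on the %s side (%d) for steady-state detection.",
                  side, nrow(rec)), class = "stomavpd_no_steady_state")
  }
  t <- rec$time_min
  g <- rec$gsw
  n <- length(t)

  best <- NULL          # latest qualifying window
  closest <- NULL       # best non-qualifying candidate, for diagnostics
  for (i in seq_len(n)) {
    j <- which(t >= t[i] & t <= t[i] + plateau_window_min)
    if (length(j) < 3) next
    if (t[max(j)] - t[i] < plateau_window_min - 1e-9) next  # window not fully spanned
    tw <- t[j]; gw <- g[j]
    mu <- mean(gw)
    slope <- stats::cov(tw, gw) / stats::var(tw)
    sdev <- sd(gw)
    cv <- if (mu > 0) sdev / mu else Inf
    cand <- list(
      level = mu, window = c(t[i], t[max(j)]), residual_slope = slope,
      sd = sdev, se = sdev / sqrt(length(j)), cv = cv, n = length(j)
    )
    if (abs(slope) <= slope_tol && cv <= cv_tol) {
      best <- cand  # keep scanning: latest start wins
    } else {
      score <- abs(slope) / slope_tol + cv / cv_tol
      if (is.null(closest) || score < closest$score) {
        closest <- c(cand, list(score = score))
      }
    }
  }
  if (is.null(best)) {
    diag <- if (is.null(closest)) "no window spans the requested length" else {
      sprintf("best candidate: window [%g, %g], |slope| %.3g (tol %.3g), CV %.3g (tol %.3g)",
              closest$window[1], closest$window[2], abs(closest$residual_slope),
              slope_tol, closest$cv, cv_tol)
    }
    abort(sprintf("No steady state found on the %s side; %s.", side, diag),
          class = "stomavpd_no_steady_state")
  }
  structure(best, class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> level %.4f mol m-2 s-1 over [%g, %g] min (slope %.2g, CV %.2g, n=%d)\n",
    x$level, x$window[1], x$window[2], x$residual_slope, x$cv, x$n
  ))
  invisible(x)
}

# First time g crosses `level` from above among unmasked post-step records,
# by linear interpolation between the bracketing per-minute samples.
# Returns NA when no crossing occurs before the end of the trace.
first_crossing_from_above <- function(time_min, gsw, level) {
  above <- gsw > level
  for (k in seq_len(length(gsw) - 1)) {
    if (above[k] && !above[k + 1]) {
      if (gsw[k] == gsw[k + 1]) return(time_min[k + 1])
      frac <- (gsw[k] - level) / (gsw[k] - gsw[k + 1])
      return(time_min[k] + frac * (time_min[k + 1] - time_min[k]))
    }
  }
  NA_real_
}

#' Wrong-way-response amplitude
#'
#' The transient conductance overshoot that follows a VPD increase: peak
#' unmasked conductance inside the search window minus the conductance at
#' time zero (`g_t0`, the pre-step plateau level). The search window runs
#' from the mask edge to `min(wwr_search_max_min, first baseline crossing)`
#' so that late noise excursions after closure never masquerade as the peak.
#' The amplitude may be zero or negative when the true peak falls inside the
#' artifact mask; it is reported as-is (clipping would hide the masked-peak
#' case) and flagged.
#'
#' @param trace A masked [gx_trace()].
#' @param g_t0 Conductance at time zero (pre-step plateau level).
#' @param mask_min Mask length, minutes.
#' @param wwr_search_max_min Upper bound of the peak search, minutes.
#' @return List with `amplitude`, `peak_time_min`, `flags` (character;
#'   `"no_resolvable_overshoot"` when amplitude <= 0).
#' @export
wwr_amplitude <- function(trace, g_t0, mask_min = 3, wwr_search_max_min = 20) {
  stopifnot(inherits(trace, "gx_trace"))
  rec <- unmasked(trace)
  post <- rec[rec$time_min >= 0, ]
  if (nrow(post) == 0) abort("Empty post-step window: cannot measure WWR amplitude.")
  crossing <- first_crossing_from_above(post$time_min, post$gsw, g_t0)
  upper <- min(wwr_search_max_min, if (is.na(crossing)) Inf else crossing)
  win <- post[post$time_min <= upper + 1e-9, ]
  if (nrow(win) == 0) win <- post[1, ]
  k <- which.max(win$gsw)
  amplitude <- win$gsw[k] - g_t0
  flags <- if (amplitude <= 0) "no_resolvable_overshoot" else character(0)
  list(amplitude = amplitude, peak_time_min = win$time_min[k], flags = flags)
}

#' Wrong-way-response duration
#'
#' How long the overshoot lasts, with the criterion chosen by where the new
#' steady state sits relative to baseline:
#'
#' * **return_to_baseline** (post level below `g_t0` minus the band): the
#'   first post-mask time conductance crosses `g_t0` from above, linearly
#'   interpolated between the bracketing per-minute samples.
#' * **reach_new_steady_state** (post level above `g_t0` plus the band): the
#'   first post-mask time the trace enters the band around the new level and
#'   stays inside it for at least `settle_persist_min` consecutive minutes.
#' * **degenerate** (post level within the band of `g_t0`): the first time
#'   the trace re-enters and stays within the band around `g_t0` — zero for
#'   a trace that never left it — falling back to the post plateau's window
#'   start when no such re-entry resolves.
#'
#' @param trace A masked [gx_trace()].
#' @param g_ss_pre,g_ss_post `steady_state` objects from
#'   [detect_steady_state()].
#' @param equality_band Half-width of the baseline-equality band,
#'   mol m^-2 s^-1.
#' @param settle_persist_min Minutes a trace must remain in-band to settle.
#' @param g_t0 Conductance at time zero; defaults to the pre plateau level.
#' @return List with `duration_min`, `criterion`, `flags`.
#' @export
wwr_duration <- function(trace, g_ss_pre, g_ss_post, equality_band,
                         settle_persist_min = 3, g_t0 = g_ss_pre$level) {
  stopifnot(inherits(trace, "gx_trace"),
            inherits(g_ss_pre, "steady_state"),
            inherits(g_ss_post, "steady_state"))
  rec <- unmasked(trace)
  post <- rec[rec$time_min >= 0, ]
  if (nrow(post) == 0) abort("Empty post-step window: cannot measure WWR duration.")
  lvl <- g_ss_post$level
  flags <- character(0)

  if (lvl < g_t0 - equality_band) {
    # criterion A: return to baseline
    if (post$gsw[1] <= g_t0) {
      # already at/below baseline at the first usable sample: the crossing is
      # hidden inside the artifact mask
      return(list(duration_min = post$time_min[1], criterion = "return_to_baseline",
                  flags = "crossing_in_mask"))
    }
    crossing <- first_crossing_from_above(post$time_min, post$gsw, g_t0)
    if (is.na(crossing)) {
      abort("Baseline never re-attained before the end of the trace (criterion return_to_baseline).",
            class = "stomavpd_no_crossing")
    }
    return(list(duration_min = crossing, criterion = "return_to_baseline", flags = flags))
  }

  if (lvl > g_t0 + equality_band) {
    # criterion B: settle into the new (higher) steady state
    settle <- first_settling_time(post$time_min, post$gsw, lvl, equality_band,
                                  settle_persist_min)
    if (is.na(settle)) {
      # plateau detection succeeded, so its own window start is in-band
      settle <- g_ss_post$window[1]
      flags <- "settling_from_plateau_window"
    }
    return(list(duration_min = settle, criterion = "reach_new_steady_state", flags = flags))
  }

  # degenerate: new steady state indistinguishable from baseline; a trace
  # whose unmasked post-step records never leave the band has duration 0
  all_post <- trace[trace$time_min >= 0, ]
  in_band <- abs(all_post$gsw - g_t0) <= equality_band
  if (all(in_band[!all_post$masked])) {
    return(list(duration_min = 0, criterion = "degenerate", flags = "degenerate"))
  }
  settle <- first_settling_time(post$time_min, post$gsw, g_t0, equality_band,
                                settle_persist_min)
  if (is.na(settle)) settle <- g_ss_post$window[1]
  list(duration_min = settle, criterion = "degenerate", flags = "degenerate")
}

# First time the series enters the band [level - band, level + band] and
# remains inside it for >= persist_min consecutive minutes of samples.
first_settling_time <- function(time_min, gsw, level, band, persist_min) {
  inside <- abs(gsw - level) <= band
  n <- length(inside)
  run_start <- NA_integer_
  for (k in seq_len(n)) {
    if (inside[k]) {
      if (is.na(run_start)) run_start <- k
      if (time_min[k] - time_min[run_start] >= persist_min - 1e-9 &&
          all(inside[run_start:k])) {
        # require the run to persist to the end of the trace's in-band stretch
        # only over the persist window, not the whole remaining trace
        return(time_min[run_start])
      }
    } else {
      run_start <- NA_integer_
    }
  }
  NA_real_
}

#' Cumulative water loss during the wrong-way response
#'
#' Left Riemann sum of transpiration over the usable part of the overshoot:
#' `sum(E * dt)` over unmasked records with `mask_min <= t < duration_min`,
#' each record representing the sampling interval that follows it (`dt` in
#' seconds; per-minute logging gives 60 s per record), so a duration of 10
#' min with a 3-min mask integrates 7 minutes of transpiration. No
#' interpolation is used for cumulative sums; the artifact-masked minutes
#' are excluded by construction, so the sum starts at the mask edge.
#'
#' @param trace A masked [gx_trace()] with transpiration present.
#' @param duration_min WWR duration from [wwr_duration()].
#' @param mask_min Mask length, minutes.
#' @return List with `cumulative_water_loss` (mol m^-2) and `flags`
#'   (`"duration_inside_mask"` with a warning when `duration_min < mask_min`).
#' @export
cumulative_wwr_water_loss <- function(trace, duration_min, mask_min = 3) {
  stopifnot(inherits(trace, "gx_trace"))
  if (duration_min < mask_min) {
    warn("WWR duration ends inside the artifact mask; cumulative water loss reported as 0.")
    return(list(cumulative_water_loss = 0, flags = "duration_inside_mask"))
  }
  rec <- unmasked(trace)
  win <- rec[rec$time_min >= mask_min - 1e-9 & rec$time_min < duration_min - 1e-9, ]
  if (nrow(win) == 0) {
    return(list(cumulative_water_loss = 0, flags = "empty_integration_window"))
  }
  if (any(is.na(win$e_trans))) {
    abort("Transpiration (`e_trans`) missing inside the WWR window; cannot integrate water loss.")
  }
  dt_min <- stats::median(diff(trace$time_min))
  loss <- sum(win$e_trans) * dt_min * 60
  list(cumulative_water_loss = loss, flags = character(0))
}

#' Steady-state VPD-induced conductance change
#'
#' `g_t0 - g_ss_post`: positive values mean net stomatal closure at the new
#' steady state, negative values net opening. A response whose magnitude
#' falls within the equality band is labelled VPD-hyposensitive at steady
#' state.
#'
#' @param g_t0 Conductance at time zero (pre-step plateau level).
#' @param g_ss_post Post-step `steady_state` (or a bare level).
#' @param equality_band Half-width of the hyposensitivity band.
#' @return List with `delta_gss` and logical `hyposensitive`.
#' @examples
#' steady_state_delta(0.20, 0.12, 0.004)
#' @export
steady_state_delta <- function(g_t0, g_ss_post, equality_band = 0) {
  lvl <- if (inherits(g_ss_post, "steady_state")) g_ss_post$level else g_ss_post
  delta <- g_t0 - lvl
  list(delta_gss = delta, hyposensitive = abs(delta) <= equality_band)
}

#' Extract all wrong-way-response metrics from a trace
#'
#' Runs the full extraction chain on one trace: validates record counts,
#' applies the artifact mask, detects pre- and post-step plateaus, and
#' computes the four response statistics (WWR amplitude, WWR duration with
#' its criterion, cumulative water loss during the WWR, and the steady-state
#' conductance change). `g_t0` is the pre-step plateau level — the mean of
#' the qualifying pre-window — rather than the single sample logged at t = 0,
#' for robustness to one noisy record. The baseline-equality band is
#' `max(equality_band_pct% of g_t0, 2 * pre-plateau standard error)`.
#'
#' Deterministic: identical trace and config give identical metrics.
#'
#' @param trace A [gx_trace()].
#' @param protocol Optional [step_protocol()] whose `mask_min` overrides the
#'   config's.
#' @param config A [wwr_config()].
#' @return A `wwr_metrics` object; see [tidy.wwr_metrics()] for the tabular
#'   form.
#' @examples
#' tr <- simulate_trace(trace_params(seed = 1))
#' extract_wwr(tr)
#' @export
extract_wwr <- function(trace, protocol = NULL, config = wwr_config()) {
  stopifnot(inherits(trace, "gx_trace"), inherits(config, "wwr_config"))
  mask_min <- if (!is.null(protocol)) protocol$mask_min else config$mask_min
  trace <- apply_artifact_mask(trace, mask_min = mask_min)

  n_pre <- sum(trace$time_min < 0)
  n_post <- sum(trace$time_min >= 0 & !trace$masked)
  if (n_pre < 3 || n_post < 10) {
    abort(sprintf(
      "Trace too short for extraction: %d pre-step and %d usable post-step records (need >= 3 and >= 10).",
      n_pre, n_post))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed for %s: %s", name,
                    attr(trace, "sample_id"), conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }

  ss_pre <- stage("detect_steady_state(pre)", detect_steady_state(
    trace, "pre", config$plateau_window_min, config$slope_tol, config$cv_tol))
  ss_post <- stage("detect_steady_state(post)", detect_steady_state(
    trace, "post", config$plateau_window_min, config$slope_tol, config$cv_tol))
  g_t0 <- ss_pre$level
  band <- max(config$equality_band_pct / 100 * g_t0, 2 * ss_pre$se)

  amp <- stage("wwr_amplitude", wwr_amplitude(
    trace, g_t0, mask_min, config$wwr_search_max_min))
  dur <- stage("wwr_duration", wwr_duration(
    trace, ss_pre, ss_post, band, config$settle_persist_min, g_t0))
  loss <- if (all(is.na(trace$e_trans))) {
    list(cumulative_water_loss = NA_real_, flags = "no_transpiration_data")
  } else {
    stage("cumulative_wwr_water_loss",
          suppressWarnings(cumulative_wwr_water_loss(trace, dur$duration_min, mask_min)))
  }
  delta <- steady_state_delta(g_t0, ss_post, band)

  meta <- trace_meta(trace)
  structure(
    list(
      sample_id = meta$sample_id,
      genotype = meta$genotype,
      amplitude = amp$amplitude,
      peak_time_min = amp$peak_time_min,
      duration_min = dur$duration_min,
      duration_criterion = dur$criterion,
      cumulative_water_loss = loss$cumulative_water_loss,
      delta_gss = delta$delta_gss,
      hyposensitive_steady_state = delta$hyposensitive,
      g_t0 = g_t0,
      equality_band = band,
      ss_pre = ss_pre,
      ss_post = ss_post,
      mask_min = mask_min,
      flags = unique(c(amp$flags, dur$flags, loss$flags))
    ),
    class = "wwr_metrics"
  )
}

#' @export
print.wwr_metrics <- function(x, ...) {
  cat(sprintf("<wwr_metrics> %s (%s)\n", x$sample_id, x$genotype))
  cat(sprintf("  amplitude       %+.4f mol m-2 s-1 (peak at %g min)\n",
              x$amplitude, x$peak_time_min))
  cat(sprintf("  duration        %.2f min [%s]\n", x$duration_min, x$duration_criterion))
  cat(sprintf("  water loss      %s mol m-2\n",
              if (is.na(x$cumulative_water_loss)) "NA" else sprintf("%.3f", x$cumulative_water_loss)))
  cat(sprintf("  delta g_ss      %+.4f mol m-2 s-1%s\n", x$delta_gss,
              if (x$hyposensitive_steady_state) " (hyposensitive)" else ""))
  if (length(x$flags)) cat("  flags           ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a wwr_metrics object
#'
#' One row per trace with the four response statistics, criterion, baseline,
#' plateau levels and flags — the natural input to [compare_wwr()].
#'
#' @param x A `wwr_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.wwr_metrics <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    genotype = x$genotype,
    amplitude = x$amplitude,
    peak_time_min = x$peak_time_min,
    duration_min = x$duration_min,
    duration_criterion = x$duration_criterion,
    cumulative_water_loss = x$cumulative_water_loss,
    delta_gss = x$delta_gss,
    hyposensitive_steady_state = x$hyposensitive_steady_state,
    g_t0 = x$g_t0,
    g_ss_pre = x$ss_pre$level,
    g_ss_post = x$ss_post$level,
    equality_band = x$equality_band,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Glance at a wwr_metrics object
#'
#' @param x A `wwr_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the four headline statistics.
#' @export
glance.wwr_metrics <- function(x, ...) {
  tibble(
    amplitude = x$amplitude,
    duration_min = x$duration_min,
    cumulative_water_loss = x$cumulative_water_loss,
    delta_gss = x$delta_gss
  )
}
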