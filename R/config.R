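#' Extraction and comparison configuration
#'
#' All tunable tolerances of the pipeline in one validated record, with
#' defaults mirroring the measurement protocol the package targets
#' (per-minute logging, a 3-minute artifact mask, 40-60 minute horizon).
#'
#' @param mask_min Artifact mask length after the step, minutes (default 3).
#' @param plateau_window_min Sliding-window length used for steady-state
#'   detection, minutes (default 10; steady state typically needs 20-30 min
#'   to establish, so a 10-min plateau is a conservative certificate).
#' @param slope_tol Maximum |OLS slope| of a qualifying plateau window,
#'   mol m^-2 s^-1 per minute (default 0.001).
#' @param cv_tol Maximum coefficient of variation of a qualifying window
#'   (default 0.05).
#' @param equality_band_pct Half-width of the baseline-equality band as a
#'   percent of the pre-step level (default 2); the band actually used is
#'   `max(equality_band_pct% of g_t0, 2 * plateau standard error)`.
#' @param wwr_search_max_min Upper bound of the peak-search window, minutes
#'   after the step (default 20; observed overshoot durations are ~9-17 min).
#' @param settle_persist_min Consecutive minutes a trace must remain inside
#'   the post-steady-state band to count as settled (default 3).
#' @param star_thresholds Decreasing p-value cutpoints for significance
#'   coding `*`, `**`, `***` (default `c(0.05, 0.01, 0.0001)`).
#' @param dialect Default input dialect for file-reading stages.
#' @param seed Optional integer seed recorded for pipeline provenance.
#' @return A `wwr_config` object (named list).
#' @examples
#' wwr_config()
#' @export
wwr_config <- function(mask_min = 3,
                       plateau_window_min = 10,
                       slope_tol = 0.001,
                       cv_tol = 0.05,
                       equality_band_pct = 2,
                       wwr_search_max_min = 20,
                       settle_persist_min = 3,
                       star_thresholds = c(0.05, 0.01, 0.0001),
                       dialect = c("simple_csv", "li6800_like"),
                       seed = NULL) {
  dialect <- match.arg(dialect)
  num1 <- function(x, nm, min_ok = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (strict && x <= min_ok) || (!strict && x < min_ok)) {
      abort(sprintf("`%s` must be a single finite number %s %g.", nm,
                    if (strict) ">" else ">=", min_ok))
    }
  }
  num1(mask_min, "mask_min", 0, strict = FALSE)
  num1(plateau_window_min, "plateau_window_min")
  num1(slope_tol, "slope_tol")
  num1(cv_tol, "cv_tol")
  num1(equality_band_pct, "equality_band_pct")
  num1(wwr_search_max_min, "wwr_search_max_min")
  num1(settle_persist_min, "settle_persist_min")
  if (length(star_thresholds) != 3 || any(diff(star_thresholds) >= 0) ||
      any(star_thresholds <= 0) || any(star_thresholds >= 1)) {
    abort("`star_thresholds` must be 3 strictly decreasing p-value cutpoints in (0, 1).")
  }
  structure(
    list(mask_min = mask_min, plateau_window_min = plateau_window_min,
         slope_tol = slope_tol, cv_tol = cv_tol,
         equality_band_pct = equality_band_pct,
         wwr_search_max_min = wwr_search_max_min,
         settle_persist_min = settle_persist_min,
         star_thresholds = star_thresholds, dialect = dialect, seed = seed),
    class = "wwr_config"
  )
}

#' @export
print.wwr_config <- function(x, ...) {
  cat("<wwr_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
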