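#' Significance stars from a p-value
#'
#' Coding used in the figure captions this pipeline reproduces: `*` for
#' p < 0.05, `**` for p < 0.01, `***` for p < 0.0001 (as printed — stricter
#' than the conventional 0.001), `ns` otherwise. Thresholds are configurable
#' but must be strictly decreasing.
#'
#' @param p P-value(s) in `[0, 1]`. Vectorized.
#' @param thresholds Decreasing cutpoints for `*`, `**`, `***`.
#' @return Character vector in `{"ns", "*", "**", "***"}`.
#' @examples
#' stars_from_p(c(0.2, 0.04, 0.005, 5e-5))
#' @export
stars_from_p <- function(p, thresholds = c(0.05, 0.01, 0.0001)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must be probabilities in [0, 1].")
  }
  if (length(thresholds) != 3 || any(diff(thresholds) >= 0)) {
    abort("`thresholds` must be 3 strictly decreasing cutpoints.")
  }
  dplyr::case_when(
    p < thresholds[3] ~ "***",
    p < thresholds[2] ~ "**",
    p < thresholds[1] ~ "*",
    .default = "ns"
  )
}

#' Compare one metric between a genotype and its reference
#'
#' Two-sample t-test of a response statistic (amplitude, duration, water
#' loss, or steady-state change) between a mutant/cultivar and its reference
#' line, with significance coded as stars. Welch's unequal-variance form is
#' the default — the safer choice at the n of 3-5 plants typical of these
#' experiments — with the pooled-variance form available.
#'
#' @param ref_values,geno_values Numeric vectors of per-plant metric values
#'   (each n >= 2, finite).
#' @param metric_name Label for the compared metric.
#' @param reference,genotype Group labels.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param star_thresholds Cutpoints passed to [stars_from_p()].
#' @return A one-row tibble: `metric_name`, `reference`, `genotype`, `n_ref`,
#'   `n_geno`, `estimate_ref`, `estimate_geno`, `t_stat`, `df`, `p_value`,
#'   `stars`.
#' @examples
#' compare_metric(c(9, 10, 8), c(13, 15, 14), "duration_min")
#' @export
compare_metric <- function(ref_values, geno_values, metric_name = "metric",
                           reference = "reference", genotype = "genotype",
                           var_equal = FALSE,
                           star_thresholds = c(0.05, 0.01, 0.0001)) {
  check_sample <- function(x, nm) {
    if (!is.numeric(x) || length(x) < 2 || any(!is.finite(x))) {
      abort(sprintf("`%s` must be a numeric sample of n >= 2 finite values.", nm))
    }
  }
  check_sample(ref_values, "ref_values")
  check_sample(geno_values, "geno_values")
  if (sd(ref_values) == 0 && sd(geno_values) == 0) {
    abort("Both samples have zero variance; the t statistic is undefined.")
  }
  ht <- t.test(geno_values, ref_values, var.equal = var_equal)
  p <- ht$p.value
  tibble(
    metric_name = metric_name,
    reference = reference,
    genotype = genotype,
    n_ref = length(ref_values),
    n_geno = length(geno_values),
    estimate_ref = mean(ref_values),
    estimate_geno = mean(geno_values),
    t_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = p,
    stars = stars_from_p(p, star_thresholds)
  )
}

#' Compare all WWR metrics of each genotype against a reference
#'
#' Takes a tidy metrics table (one row per trace, as produced by mapping
#' [tidy()] over [extract_wwr()] results) and runs [compare_metric()] for
#' every non-reference genotype and every requested metric. No
#' multiple-testing correction is applied by default, matching the practice
#' of reporting per-comparison t-tests; Holm adjustment is available.
#'
#' @param metrics_df Tibble with a `genotype` column and metric columns.
#' @param reference Reference genotype name present in `metrics_df`.
#' @param metrics Metric column names to compare.
#' @param var_equal,star_thresholds Passed to [compare_metric()].
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A tibble of comparison rows.
#' @export
compare_wwr <- function(metrics_df,
                        reference = "wildtype",
                        metrics = c("amplitude", "duration_min",
                                    "cumulative_water_loss", "delta_gss"),
                        var_equal = FALSE,
                        star_thresholds = c(0.05, 0.01, 0.0001),
                        p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  metrics_df <- as_tibble(metrics_df)
  if (!"genotype" %in% names(metrics_df)) abort("`metrics_df` needs a `genotype` column.")
  missing_metrics <- setdiff(metrics, names(metrics_df))
  if (length(missing_metrics)) {
    abort(paste0("Metric column(s) not found: ", paste(missing_metrics, collapse = ", "), "."))
  }
  if (!reference %in% metrics_df$genotype) {
    abort(paste0("Reference genotype '", reference, "' not present in the table."))
  }
  others <- setdiff(unique(metrics_df$genotype), reference)
  out <- purrr::map_dfr(others, function(geno) {
    purrr::map_dfr(metrics, function(m) {
      compare_metric(
        metrics_df[[m]][metrics_df$genotype == reference],
        metrics_df[[m]][metrics_df$genotype == geno],
        metric_name = m, reference = reference, genotype = geno,
        var_equal = var_equal, star_thresholds = star_thresholds
      )
    })
  })
  if (p_adjust == "holm" && nrow(out)) {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$stars <- stars_from_p(out$p_value, star_thresholds)
  }
  out
}

#' Percent change and sensitivity class for a cultivar screen
#'
#' The porometer screen logic: percent reduction in conductance after a
#' sustained high-VPD exposure, `100 * (g_before - g_after) / g_before`, and
#' the hyposensitivity rule — a cultivar whose reduction is *less than 75%*
#' is classed `hyposensitive`, strictly (a reduction of exactly 75% is
#' `sensitive`).
#'
#' @param screen_df Tibble with columns `cultivar`, `g_before`, `g_after`
#'   (panel-mean conductances, mol m^-2 s^-1; `g_before` > 0).
#' @param threshold_pct Hyposensitivity boundary, percent (default 75).
#' @return The input with `pct_change` and `sensitivity_class` appended.
#' @examples
#' screen_percent_change(tibble::tibble(
#'   cultivar = c("A", "B"), g_before = c(0.5, 0.4), g_after = c(0.2, 0.0)))
#' @export
screen_percent_change <- function(screen_df, threshold_pct = 75) {
  screen_df <- as_tibble(screen_df)
  needed <- c("cultivar", "g_before", "g_after")
  missing_cols <- setdiff(needed, names(screen_df))
  if (length(missing_cols)) {
    abort(paste0("Screen table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (any(!is.finite(screen_df$g_before)) || any(screen_df$g_before <= 0)) {
    abort("`g_before` must be positive and finite for every cultivar.")
  }
  if (any(!is.finite(screen_df$g_after)) || any(screen_df$g_after < 0)) {
    abort("`g_after` must be non-negative and finite.")
  }
  dplyr::mutate(
    screen_df,
    pct_change = 100 * (.data$g_before - .data$g_after) / .data$g_before,
    sensitivity_class = dplyr::if_else(.data$pct_change < threshold_pct,
                                       "hyposensitive", "sensitive")
  )
}

#' Aggregate replicate porometer readings
#'
#' Porometer surveys take several spot readings per plant (eight per plant in
#' the protocol this mirrors) on a few plants per cultivar. Aggregation is
#' per-plant-first: readings are averaged within each plant, then the panel
#' mean and SEM are computed over plant means, so n counts plants, not
#' readings.
#'
#' @param readings Tibble with columns `cultivar`, `plant`, `phase`
#'   (`"before"`/`"after"`), `reading` (conductance, mol m^-2 s^-1).
#' @param k_expected Expected readings per plant and phase; a mismatch warns
#'   but computation proceeds.
#' @return A tibble with one row per cultivar and phase: `mean`, `sem`,
#'   `n_plants`.
#' @export
aggregate_replicates <- function(readings, k_expected = 8) {
  readings <- as_tibble(readings)
  needed <- c("cultivar", "plant", "phase", "reading")
  missing_cols <- setdiff(needed, names(readings))
  if (length(missing_cols)) {
    abort(paste0("Readings table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(readings) == 0) abort("Readings table is empty.")
  if (any(!is.finite(readings$reading))) abort("`reading` must be finite.")

  per_plant <- readings |>
    dplyr::group_by(.data$cultivar, .data$phase, .data$plant) |>
    dplyr::summarise(plant_mean = mean(.data$reading), k = dplyr::n(),
                     .groups = "drop")
  if (any(per_plant$k != k_expected)) {
    warn(sprintf("Some plants have a number of readings different from k_expected = %d.",
                 k_expected))
  }
  per_plant |>
    dplyr::group_by(.data$cultivar, .data$phase) |>
    dplyr::summarise(
      mean = mean(.data$plant_mean),
      sem = if (dplyr::n() > 1) sd(.data$plant_mean) / sqrt(dplyr::n()) else NA_real_,
      n_plants = dplyr::n(),
      .groups = "drop"
    )
}

#' Run the cultivar sensitivity screen from raw readings
#'
#' Convenience composition: [aggregate_replicates()] per cultivar and phase,
#' reshape to before/after, then [screen_percent_change()].
#'
#' @param readings As in [aggregate_replicates()]; `phase` must contain
#'   `"before"` and `"after"`.
#' @param k_expected,threshold_pct Passed through.
#' @return A tibble with one row per cultivar: panel means, `pct_change`,
#'   `sensitivity_class`.
#' @export
run_screen <- function(readings, k_expected = 8, threshold_pct = 75) {
  agg <- aggregate_replicates(readings, k_expected = k_expected)
  if (!all(c("before", "after") %in% agg$phase)) {
    abort("`phase` must contain both 'before' and 'after' readings.")
  }
  wide <- agg |>
    dplyr::select("cultivar", "phase", "mean") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "mean") |>
    dplyr::rename(g_before = "before", g_after = "after")
  screen_percent_change(wide, threshold_pct = threshold_pct)
}
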