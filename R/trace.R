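#' Gas-exchange trace
#'
#' A `gx_trace` is a tibble of per-record gas-exchange measurements around a
#' VPD step, with time re-based so the step occurs at `time_min = 0`. Columns:
#'
#' * `time_min` — minutes relative to the step (strictly increasing);
#' * `gsw` — stomatal conductance to water vapor, mol m^-2 s^-1 (>= 0);
#' * `e_trans` — transpiration, mol m^-2 s^-1 (>= 0; may be `NA`);
#' * `t_leaf_c`, `t_air_c`, `rh_pct`, `vpd_kpa` — environment (may be `NA`);
#' * `masked` — logical, `TRUE` for records inside the instrument-artifact
#'   exclusion window (never contribute to any metric).
#'
#' Trace-level metadata (`sample_id`, `genotype`, `masked_until_min`, and any
#' auxiliary columns preserved from a vendor file) live in attributes.
#'
#' @param records A data frame with at least `time_min` and `gsw`; missing
#'   optional columns are filled with `NA`.
#' @param sample_id,genotype Identifying labels.
#' @param masked_until_min Upper edge (exclusive) of the applied artifact mask
#'   in minutes; 0 means no mask applied yet.
#' @param aux Optional tibble of auxiliary (unmapped) columns, row-aligned
#'   with `records`.
#' @return A `gx_trace` (tibble subclass).
#' @examples
#' gx_trace(tibble::tibble(time_min = -2:5, gsw = 0.2))
#' @export
gx_trace <- function(records, sample_id = "sample", genotype = "unknown",
                     masked_until_min = 0, aux = NULL) {
  records <- as_tibble(records)
  needed <- c("time_min", "gsw")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Trace records are missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  optional <- c("e_trans", "t_leaf_c", "t_air_c", "rh_pct", "vpd_kpa")
  for (col in optional) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (!"masked" %in% names(records)) records$masked <- FALSE
  records <- records[, c(needed, optional, "masked")]
  validate_gx_records(records)
  structure(
    records,
    sample_id = sample_id,
    genotype = genotype,
    masked_until_min = masked_until_min,
    aux = aux,
    class = c("gx_trace", class(tibble())))
}

validate_gx_records <- function(records) {
  tm <- records$time_min
  if (!is.numeric(tm) || any(!is.finite(tm))) {
    abort("`time_min` must be finite numeric minutes.")
  }
  if (any(diff(tm) <= 0)) {
    abort("`time_min` must be strictly increasing (non-monotone time detected).")
  }
  if (!is.numeric(records$gsw) || any(!is.finite(records$gsw))) {
    abort("`gsw` must be finite numeric.")
  }
  if (any(records$gsw < 0)) {
    abort("`gsw` must be non-negative.")
  }
  e <- records$e_trans
  if (any(!is.na(e) & e < 0)) {
    abort("`e_trans` must be non-negative where present.")
  }
  invisible(records)
}

#' @export
print.gx_trace <- function(x, ...) {
  cat(sprintf(
    "<gx_trace> %s (%s): %d records, t in [%g, %g] min, mask [0, %g) min\n",
    attr(x, "sample_id"), attr(x, "genotype"), nrow(x),
    min(x$time_min), max(x$time_min), attr(x, "masked_until_min")
  ))
  NextMethod()
}

trace_meta <- function(trace) {
  list(
    sample_id = attr(trace, "sample_id"),
    genotype = attr(trace, "genotype"),
    masked_until_min = attr(trace, "masked_until_min")
  )
}

# records usable by metrics: masked ones are excluded everywhere downstream
unmasked <- function(trace) trace[!trace$masked, , drop = FALSE]

#' Step protocol
#'
#' The imposed environmental step: pre- and post-step air states, the step
#' time in the raw log's clock (minutes), and the artifact mask length. The
#' default protocol mirrors a common chamber routine: 22 °C throughout, RH
#' dropped from 70% to 15%, with the first 3 minutes after the step excluded
#' because chamber re-equilibration corrupts apparent conductance there.
#'
#' @param pre_air,post_air [air_state()] before/after the step.
#' @param step_time_min Step time on the raw log clock; re-based to 0.
#' @param mask_min Artifact mask length in minutes (half-open `[0, mask_min)`).
#' @return A `step_protocol` object.
#' @examples
#' step_protocol()
#' @export
step_protocol <- function(pre_air = air_state(22, 70),
                          post_air = air_state(22, 15),
                          step_time_min = 0,
                          mask_min = 3) {
  if (!inherits(pre_air, "air_state") || !inherits(post_air, "air_state")) {
    abort("`pre_air` and `post_air` must be air_state objects.")
  }
  if (!is.numeric(mask_min) || length(mask_min) != 1 || !is.finite(mask_min) || mask_min < 0) {
    abort("`mask_min` must be a single non-negative number of minutes.")
  }
  structure(
    list(pre_air = pre_air, post_air = post_air,
         step_time_min = step_time_min, mask_min = mask_min),
    class = "step_protocol"
  )
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> %.1f°C/%.0f%% -> %.1f°C/%.0f%% (VPD %.2f -> %.2f kPa), mask %g min\n",
    x$pre_air$temperature_c, x$pre_air$relative_humidity_pct,
    x$post_air$temperature_c, x$post_air$relative_humidity_pct,
    vpd_air(x$pre_air)$kpa, vpd_air(x$post_air)$kpa, x$mask_min
  ))
  invisible(x)
}

#' Apply the instrument-artifact mask
#'
#' Flags records in the half-open window `[0, mask_min)` after the step as
#' excluded. Abrupt humidity changes transiently corrupt the infrared gas
#' analyzer's conductance estimate while the chamber re-equilibrates;
#' artificial-leaf controls show the corruption is confined to the first
#' minutes, so those records never contribute to any downstream metric.
#' Pre-step records are never masked. The record at exactly `t = mask_min` is
#' retained: the usable window starts there. Idempotent.
#'
#' @param trace A [gx_trace()].
#' @param protocol A [step_protocol()] carrying `mask_min`, or `NULL` to use
#'   `mask_min` directly.
#' @param mask_min Mask length in minutes, used when `protocol` is `NULL`.
#' @return The trace with `masked` set and `masked_until_min` recorded.
#' @examples
#' tr <- gx_trace(tibble::tibble(time_min = -3:10, gsw = 0.2))
#' apply_artifact_mask(tr, mask_min = 3)
#' @export
apply_artifact_mask <- function(trace, protocol = NULL, mask_min = 3) {
  stopifnot(inherits(trace, "gx_trace"))
  if (!is.null(protocol)) {
    if (!inherits(protocol, "step_protocol")) {
      abort("`protocol` must be a step_protocol object.")
    }
    mask_min <- protocol$mask_min
  }
  if (mask_min < 0) abort("`mask_min` must be non-negative.")
  trace$masked <- trace$time_min >= 0 & trace$time_min < mask_min
  attr(trace, "masked_until_min") <- mask_min
  trace
}
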