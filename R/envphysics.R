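#' Saturation vapor pressure (Tetens)
#'
#' Empirical saturation vapor pressure of water over a flat surface,
#' `esat(T) = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa, the Tetens
#' approximation commonly used in crop and leaf micrometeorology. Accurate to
#' well under 1% over the physiological range of leaf temperatures.
#'
#' @param temperature_c Air or leaf temperature in degrees Celsius. Vectorized.
#'   Must be finite and above -237.3 (the Tetens singularity).
#' @return Saturation vapor pressure in kPa, same length as `temperature_c`.
#' @examples
#' saturation_vapor_pressure(c(0, 22, 28))
#' @export
saturation_vapor_pressure <- function(temperature_c) {
  if (!is.numeric(temperature_c) || length(temperature_c) == 0) {
    abort("`temperature_c` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(temperature_c))) {
    abort("`temperature_c` contains non-finite values; temperatures must be finite numbers in degrees Celsius.")
  }
  if (any(temperature_c <= -237.3)) {
    abort("`temperature_c` must exceed -237.3 °C (Tetens formula singularity).")
  }
  0.6108 * exp(17.27 * temperature_c / (temperature_c + 237.3))
}

#' Air state (temperature + relative humidity)
#'
#' Light-weight record of the chamber (or ambient) air condition used to
#' impose a VPD step: temperature in degrees Celsius and relative humidity in
#' percent.
#'
#' @param temperature_c Air temperature, degrees Celsius, in `[-20, 60]`.
#' @param relative_humidity_pct Relative humidity, percent, in `[0, 100]`.
#' @return An object of class `air_state` (a named list).
#' @examples
#' air_state(22, 15)
#' @export
air_state <- function(temperature_c, relative_humidity_pct) {
  if (!is.numeric(temperature_c) || length(temperature_c) != 1 || !is.finite(temperature_c)) {
    abort("`temperature_c` must be a single finite number.")
  }
  if (temperature_c < -20 || temperature_c > 60) {
    abort("`temperature_c` must lie in [-20, 60] °C.")
  }
  if (!is.numeric(relative_humidity_pct) || length(relative_humidity_pct) != 1 ||
      !is.finite(relative_humidity_pct)) {
    abort("`relative_humidity_pct` must be a single finite number.")
  }
  if (relative_humidity_pct < 0 || relative_humidity_pct > 100) {
    abort("`relative_humidity_pct` must lie in [0, 100].")
  }
  structure(
    list(temperature_c = temperature_c, relative_humidity_pct = relative_humidity_pct),
    class = "air_state"
  )
}

#' @export
print.air_state <- function(x, ...) {
  cat(sprintf(
    "<air_state> %.1f °C, %.1f%% RH (VPD %.4f kPa, air basis)\n",
    x$temperature_c, x$relative_humidity_pct, vpd_air(x)$kpa
  ))
  invisible(x)
}

new_vpd_value <- function(kpa, basis) {
  structure(list(kpa = kpa, basis = basis), class = "vpd_value")
}

#' @export
print.vpd_value <- function(x, ...) {
  cat(sprintf("<vpd_value> %.4f kPa (%s basis)\n", x$kpa, x$basis))
  invisible(x)
}

#' Air-basis vapor pressure deficit
#'
#' VPD of the air itself: `esat(T_air) * (1 - RH/100)`. This is the quantity a
#' chamber controller targets when it sets temperature and relative humidity.
#'
#' @param state An [air_state()], or a temperature in degrees Celsius when
#'   `relative_humidity_pct` is supplied separately.
#' @param relative_humidity_pct Relative humidity in percent, only when `state`
#'   is given as a bare temperature.
#' @return A `vpd_value`: list with fields `kpa` and `basis = "air"`.
#' @examples
#' vpd_air(air_state(22, 15))
#' vpd_air(28, 35)
#' @export
vpd_air <- function(state, relative_humidity_pct = NULL) {
  if (!inherits(state, "air_state")) {
    state <- air_state(state, relative_humidity_pct)
  }
  kpa <- saturation_vapor_pressure(state$temperature_c) *
    (1 - state$relative_humidity_pct / 100)
  new_vpd_value(kpa, "air")
}

#' Leaf-to-air vapor pressure difference
#'
#' The driving force for transpiration: saturated vapor pressure at leaf
#' temperature minus the actual vapor pressure of the air,
#' `esat(T_leaf) - esat(T_air) * RH/100`. Reduces to [vpd_air()] when the leaf
#' is at air temperature.
#'
#' @param leaf_temperature_c Leaf temperature, degrees Celsius.
#' @param air_state An [air_state()] for the surrounding air.
#' @return A `vpd_value` with `basis = "leaf_to_air"`.
#' @examples
#' vpd_leaf_air(21, air_state(22, 70))
#' @export
vpd_leaf_air <- function(leaf_temperature_c, air_state) {
  if (!inherits(air_state, "air_state")) {
    abort("`air_state` must be an air_state object; see air_state().")
  }
  e_leaf <- saturation_vapor_pressure(leaf_temperature_c)
  e_air <- saturation_vapor_pressure(air_state$temperature_c) *
    air_state$relative_humidity_pct / 100
  new_vpd_value(e_leaf - e_air, "leaf_to_air")
}

#' Truncate a VPD value to reporting precision
#'
#' Gas-exchange protocols conventionally report chamber VPD at one or two
#' decimals. Reporting here truncates toward zero rather than rounding: a
#' computed 0.5288 kPa is reported as 0.52, and 2.4570 as 2.45. Internal
#' computation always keeps full floating precision; truncation happens only
#' at this reporting boundary.
#'
#' @param value A `vpd_value` (from [vpd_air()] / [vpd_leaf_air()]) or a bare
#'   non-negative number in kPa.
#' @param decimals Number of decimals kept, 1 or 2.
#' @return The truncated value in kPa (bare numeric).
#' @examples
#' report_vpd(vpd_air(22, 15), 1)   # 2.2
#' report_vpd(0.5288, 2)            # 0.52
#' @export
report_vpd <- function(value, decimals) {
  if (inherits(value, "vpd_value")) value <- value$kpa
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("`value` must be finite numeric kPa.")
  }
  if (!decimals %in% c(1L, 2L)) {
    abort("`decimals` must be 1 or 2.")
  }
  f <- 10^decimals
  # guard against representation error just below an exact decimal (e.g. 2.2
  # stored as 2.19999...): nudge by an epsilon far below reporting resolution
  trunc(value * f + sign(value) * 1e-9) / f
}
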