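# Column-name maps for the two supported log dialects. simple_csv is the
# package's own plain format; li6800_like tolerates vendor-style logs with a
# group-header line, a column-name line, and a units line before the data.
.simple_cols <- c(
  time_min = "time", gsw = "gsw", e_trans = "e",
  t_leaf_c = "t_leaf_c", t_air_c = "t_air_c", rh_pct = "rh_pct",
  vpd_kpa = "vpd_kpa"
)
.li6800_cols <- c(
  time_min = "elapsed", gsw = "gsw", e_trans = "E",
  t_leaf_c = "Tleaf", t_air_c = "Tair", rh_pct = "RHcham",
  vpd_kpa = "VPDleaf"
)

#' Read a gas-exchange time series
#'
#' Reads a delimited log of per-minute gas-exchange records into a
#' [gx_trace()], re-basing time so the VPD step sits at `time_min = 0`.
#'
#' Two dialects are supported. `simple_csv` is a plain CSV with a single
#' header row and lower-case canonical names (`time`, `gsw`, `e`, and
#' optionally `t_leaf_c`, `t_air_c`, `rh_pct`, `vpd_kpa`). `li6800_like`
#' emulates vendor console logs: any preamble lines, then a group-header
#' line, a column-name line using vendor names (`elapsed`, `gsw`, `E`,
#' `Tleaf`, `Tair`, `RHcham`, `VPDleaf`), a units line, then data rows.
#' Vendor names are mapped onto the canonical fields; unmapped columns are
#' preserved as auxiliary metadata on the returned trace.
#'
#' @param path Path to the delimited text file.
#' @param dialect `"simple_csv"` or `"li6800_like"`.
#' @param step_time_min Time of the VPD step on the file's own clock, in
#'   minutes; subtracted so the step is at 0.
#' @param sample_id,genotype Labels attached to the trace.
#' @param delim Field delimiter (`","` default; use `"\t"` for TSV).
#' @return A [gx_trace()] (no mask applied; see [apply_artifact_mask()]).
#' @export
read_trace <- function(path, dialect = c("simple_csv", "li6800_like"),
                       step_time_min = 0, sample_id = NULL, genotype = "unknown",
                       delim = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("Trace file not found: ", path))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  if (dialect == "simple_csv") {
    raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                             show_col_types = FALSE, progress = FALSE)
    colmap <- .simple_cols
  } else {
    lines <- readLines(path, warn = FALSE)
    header_idx <- which(vapply(
      lines, function(l) any(c("gsw", "elapsed") %in% trimws(strsplit(l, delim, fixed = TRUE)[[1]])),
      logical(1), USE.NAMES = FALSE
    ))[1]
    if (is.na(header_idx)) {
      abort("li6800_like file: no column-name line containing 'gsw'/'elapsed' found.")
    }
    body <- lines[header_idx:length(lines)]
    # a units line directly after the header is dropped when its time field
    # is non-numeric (e.g. "min", "mol m-2 s-1")
    if (length(body) >= 2) {
      second <- trimws(strsplit(body[2], delim, fixed = TRUE)[[1]])
      if (all(is.na(suppressWarnings(as.numeric(second))))) body <- body[-2]
    }
    raw <- readr::read_delim(I(paste(body, collapse = "\n")), delim = delim,
                             col_types = readr::cols(.default = "c"),
                             show_col_types = FALSE, progress = FALSE)
    colmap <- .li6800_cols
  }

  missing_cols <- setdiff(colmap[c("time_min", "gsw")], names(raw))
  if (length(missing_cols)) {
    abort(paste0("Trace file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }

  present <- colmap[colmap %in% names(raw)]
  records <- tibble(.rows = nrow(raw))
  for (canon in names(present)) {
    records[[canon]] <- parse_numeric_col(raw[[present[[canon]]]], present[[canon]])
  }
  aux_names <- setdiff(names(raw), present)
  aux <- if (length(aux_names)) raw[, aux_names, drop = FALSE] else NULL

  records$time_min <- records$time_min - step_time_min
  gx_trace(records, sample_id = sample_id, genotype = genotype, aux = aux)
}

parse_numeric_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" & toupper(trimws(x)) != "NA")
  if (length(bad)) {
    abort(sprintf("Non-numeric value in column '%s' at data row %d: '%s'.",
                  name, bad[1], x[bad[1]]))
  }
  out
}

#' Write a gas-exchange trace as simple_csv
#'
#' Writes the canonical columns to a plain CSV readable by
#' `read_trace(dialect = "simple_csv")`. Full double precision is preserved,
#' so a write/read cycle reproduces the trace record-for-record.
#'
#' @param trace A [gx_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gx_trace"))
  out <- tibble(
    time = trace$time_min, gsw = trace$gsw, e = trace$e_trans,
    t_leaf_c = trace$t_leaf_c, t_air_c = trace$t_air_c,
    rh_pct = trace$rh_pct, vpd_kpa = trace$vpd_kpa
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

.metrics_required <- c(
  "sample_id", "genotype", "amplitude", "duration_min", "duration_criterion",
  "cumulative_water_loss", "delta_gss", "g_t0"
)

metrics_to_list <- function(m) {
  stopifnot(inherits(m, "wwr_metrics"))
  x <- unclass(m)
  x$ss_pre <- unclass(x$ss_pre)
  x$ss_post <- unclass(x$ss_post)
  x
}

list_to_metrics <- function(x) {
  missing_fields <- setdiff(.metrics_required, names(x))
  if (length(missing_fields)) {
    abort(paste0("Metrics record is missing field(s): ",
                 paste(missing_fields, collapse = ", "), "."))
  }
  for (side in c("ss_pre", "ss_post")) {
    if (!is.null(x[[side]])) class(x[[side]]) <- "steady_state"
  }
  x$flags <- as.character(x$flags %||% character(0))
  structure(x, class = "wwr_metrics")
}

#' Serialize WWR metrics to JSON
#'
#' Writes one `wwr_metrics` object, or a list of them, as structured JSON at
#' full double precision so that [read_metrics()] round-trips losslessly.
#'
#' @param metrics A `wwr_metrics` object (from [extract_wwr()]) or a list of
#'   them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  batch <- if (inherits(metrics, "wwr_metrics")) list(metrics) else metrics
  ok <- vapply(batch, inherits, logical(1), what = "wwr_metrics")
  if (!all(ok)) abort("`metrics` must be a wwr_metrics object or a list of them.")
  payload <- purrr::map(batch, metrics_to_list)
  # I(17): doubles need 17 significant digits to round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read WWR metrics from JSON
#'
#' Inverse of [write_metrics()]. Validates that every record carries the
#' mandatory fields and errors naming any that are absent.
#'
#' @param path Path written by [write_metrics()].
#' @return A list of `wwr_metrics` objects (length 1 for a single record).
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) abort(paste0("Metrics file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  purrr::map(payload, list_to_metrics)
}
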