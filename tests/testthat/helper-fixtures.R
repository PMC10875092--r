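# Hand-constructed trace fixtures, built in code at test time.

# Quick trace from vectors; e_trans defaults to gsw-proportional so the
# cumulative stage always has data.
make_trace <- function(time_min, gsw, e_trans = gsw * 0.02,
                       sample_id = "fixture", genotype = "fixture") {
  gx_trace(
    tibble::tibble(time_min = time_min, gsw = gsw, e_trans = e_trans),
    sample_id = sample_id, genotype = genotype
  )
}

# Piecewise-linear trace: pre-step plateau at g0, then values given per
# post-step minute. Times are per-minute.
make_step_fixture <- function(g0, post_gsw, t_pre = 15, e_trans_const = NULL) {
  t <- seq(-t_pre, length(post_gsw) - 1)
  g <- c(rep(g0, t_pre), post_gsw)
  e <- if (is.null(e_trans_const)) g * 0.02 else rep(e_trans_const, length(g))
  make_trace(t, g, e)
}

# simple_csv fixture file from a data frame with columns time, gsw, e, ...
write_simple_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# li6800_like fixture: preamble, group header, vendor column names, a units
# line, then data. Same numbers as the simple_csv columns passed in.
write_li6800_like <- function(df, path = tempfile(fileext = ".csv")) {
  vendor <- c(time = "elapsed", gsw = "gsw", e = "E", t_leaf_c = "Tleaf",
              t_air_c = "Tair", rh_pct = "RHcham", vpd_kpa = "VPDleaf")
  stopifnot(all(names(df) %in% names(vendor)))
  cols <- vendor[names(df)]
  units <- c(elapsed = "min", gsw = "mol m-2 s-1", E = "mol m-2 s-1",
             Tleaf = "C", Tair = "C", RHcham = "%", VPDleaf = "kPa")[cols]
  body <- apply(df, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = ","))
  lines <- c(
    "LI-6800-style console log",
    "[Header]",
    paste(rep("SysObs", length(cols)), collapse = ","),
    paste(cols, collapse = ","),
    paste(units, collapse = ","),
    body
  )
  writeLines(lines, path)
  path
}
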