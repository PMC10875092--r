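#' Plot a gas-exchange trace
#'
#' Conductance against time with the VPD step marked at t = 0 and the
#' artifact-mask window shaded; masked records are drawn hollow.
#'
#' @param object A [gx_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gx_trace <- function(object, ...) {
  mask <- attr(object, "masked_until_min")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$gsw))
  if (mask > 0) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = mask, ymin = -Inf,
                               ymax = Inf, alpha = 0.15, fill = "grey40")
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey30") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$masked), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1), guide = "none") +
    ggplot2::labs(
      x = "Time from VPD step (min)",
      y = expression(g[sw] ~ "(mol" ~ m^-2 ~ s^-1 * ")"),
      title = attr(object, "sample_id"),
      subtitle = attr(object, "genotype")
    ) +
    ggplot2::theme_minimal()
}

#' Annotated trace + metrics diagnostic plot
#'
#' Overlays the extracted quantities on the trace: pre/post plateau windows
#' and levels, the baseline `g_t0`, the overshoot peak, and the WWR duration.
#'
#' @param trace The [gx_trace()] the metrics came from.
#' @param metrics The matching `wwr_metrics` from [extract_wwr()].
#' @return A ggplot.
#' @export
plot_wwr <- function(trace, metrics) {
  stopifnot(inherits(trace, "gx_trace"), inherits(metrics, "wwr_metrics"))
  trace <- apply_artifact_mask(trace, mask_min = metrics$mask_min)
  seg <- tibble(
    x = c(metrics$ss_pre$window[1], metrics$ss_post$window[1]),
    xend = c(metrics$ss_pre$window[2], metrics$ss_post$window[2]),
    y = c(metrics$ss_pre$level, metrics$ss_post$level),
    side = c("pre plateau", "post plateau")
  )
  autoplot(trace) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$y,
                   colour = .data$side),
      linewidth = 1, inherit.aes = FALSE
    ) +
    ggplot2::geom_hline(yintercept = metrics$g_t0, linetype = "dotted") +
    ggplot2::annotate("point", x = metrics$peak_time_min,
                      y = metrics$g_t0 + metrics$amplitude,
                      shape = 17, size = 2.5, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = metrics$duration_min,
                        linetype = "dotdash", colour = "steelblue") +
    ggplot2::labs(colour = NULL,
                  caption = sprintf("amplitude %+.3f | duration %.1f min (%s) | delta g_ss %+.3f",
                                    metrics$amplitude, metrics$duration_min,
                                    metrics$duration_criterion, metrics$delta_gss))
}

#' Plot a cultivar screen
#'
#' Percent change in conductance per cultivar, colored by sensitivity class,
#' with the hyposensitivity boundary marked.
#'
#' @param screen_df Output of [screen_percent_change()] or [run_screen()].
#' @param threshold_pct Boundary drawn (default 75).
#' @return A ggplot.
#' @export
plot_screen <- function(screen_df, threshold_pct = 75) {
  stopifnot(all(c("cultivar", "pct_change", "sensitivity_class") %in% names(screen_df)))
  ggplot2::ggplot(
    screen_df,
    ggplot2::aes(x = stats::reorder(.data$cultivar, .data$pct_change),
                 y = .data$pct_change, fill = .data$sensitivity_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Reduction in g_sw after high VPD (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
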