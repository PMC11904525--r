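# Optional ggplot2 figures (ggplot2 is a suggested dependency).

#' Plot a grand-average audio vs baseline trace
#'
#' Mean +/- SE ribbons per condition against time within the frame, with
#' the stimulus onset marked at 0.5 s.
#'
#' @param ga A [grand_average()] result.
#' @return A ggplot object.
#' @export
plot_grand_average <- function(ga) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_grand_average() requires the ggplot2 package")
  }
  tr <- ga$trace
  df <- rbind(
    data.frame(t_rel_s = tr$t_rel_s, mean = tr$mean_audio,
               se = tr$se_audio, condition = "audio"),
    data.frame(t_rel_s = tr$t_rel_s, mean = tr$mean_baseline,
               se = tr$se_baseline, condition = "baseline")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = t_rel_s, y = mean,
                                   colour = condition, fill = condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "time within frame (s)",
                  y = sprintf("pupil size (%s)",
                              if (identical(ga$norm_mode, "percent")) "% of pre-stimulus mean"
                              else "px difference from pre-stimulus mean")) +
    ggplot2::theme_minimal()
}

#' Scatter of evoked amplitude vs pre-stimulus size with fitted lines
#'
#' @param reg A [regress_prestim()] result.
#' @return A ggplot object.
#' @export
plot_regression <- function(reg) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_regression() requires the ggplot2 package")
  }
  ggplot2::ggplot(reg$points,
                  ggplot2::aes(x = pre_px, y = pdr_pct, colour = condition)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "pre-stimulus diameter (centered, px)",
                  y = "evoked amplitude (centered, %)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("t_rel_s", "condition", "se", "pdr_pct"))
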