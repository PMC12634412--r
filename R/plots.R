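#' Plot the recovery-difference histogram
#'
#' Bar chart of the binned absolute difference in percent recovery between
#' the two primary assemblers (see [diff_histogram()]).
#'
#' @param dh A tibble from [diff_histogram()].
#' @return A ggplot object.
#' @export
plot_diff_histogram <- function(dh) {
  dh$bin <- factor(dh$bin, levels = dh$bin)
  ggplot2::ggplot(dh, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "difference in percent recovery (%)",
                  y = "windows") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot percent recovery against window coverage
#'
#' Scatter of per-window percent recovery versus mean short-read depth,
#' faceted by assembly label. Useful to see the low-coverage failure mode
#' (rarely 100% recovery below a few x).
#'
#' @param recovery Long recovery tibble from [score_recovery()].
#' @param coverage Coverage summary tibble from [coverage_summary()].
#' @return A ggplot object.
#' @export
plot_recovery_coverage <- function(recovery, coverage) {
  df <- dplyr::inner_join(recovery,
                          coverage[, c("window_id", "mean_depth")],
                          by = "window_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_depth,
                                   y = .data$percent_recovery)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$assembly_label)) +
    ggplot2::labs(x = "mean window depth (x, log scale)",
                  y = "percent recovery (%)") +
    ggplot2::theme_minimal()
}
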