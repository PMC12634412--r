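#' Per-bin recovery summaries
#'
#' Aggregates window recovery for one assembly label by genome bin. Windows
#' below `min_cov` mean depth are excluded (they could not have assembled
#' for lack of data); the rest fall into one of six cells: length group
#' (not recovered 0-499 bp, partially recovered 500-999 bp, and fully
#' recovered at 1 kb) crossed with coverage class (`low` below `cov_threshold`,
#' `high` at or above it). Cell fractions are relative to the bin's
#' qualifying windows and sum to 1. Bins are ranked by decreasing fraction
#' fully recovered, ties broken by bin id.
#'
#' @param assignments A tibble with `contig_id`, `bin_id` (see
#'   [read_bin_assignments()]); unbinned contigs are simply absent.
#' @param records Long recovery tibble from [score_recovery()], filtered to
#'   (or containing) the label of interest.
#' @param coverage Coverage summary tibble from [coverage_summary()].
#' @param windows A window index tibble (to map windows to contigs).
#' @param label Assembly label to summarize; defaults to the only label in
#'   `records` (error if several and unspecified).
#' @param cov_threshold Mean-depth boundary between the low and high
#'   coverage classes (default 10; the boundary value itself is high).
#' @param min_cov Minimum mean depth for a window to enter the summary
#'   (default 1).
#' @return A `bin_summary` tibble with one row per bin: `bin_id`,
#'   `n_windows`, the six `frac_*` cells, `frac_fully`,
#'   `frac_not_recovered`, `rank`. Bins with no qualifying window carry
#'   `n_windows = 0` and `NA` fractions.
#' @export
summarize_bins <- function(assignments, records, coverage, windows,
                           label = NULL, cov_threshold = 10, min_cov = 1) {
  labs <- unique(records$assembly_label)
  if (is.null(label)) {
    if (length(labs) != 1) {
      stop("records contain several assembly labels; pass `label`")
    }
    label <- labs
  }
  rec <- records[records$assembly_label == label, ]
  dat <- rec %>%
    dplyr::inner_join(windows[, c("window_id", "contig_id")],
                      by = "window_id") %>%
    dplyr::inner_join(assignments, by = "contig_id") %>%
    dplyr::inner_join(coverage[, c("window_id", "mean_depth")],
                      by = "window_id") %>%
    dplyr::filter(.data$mean_depth >= min_cov) %>%
    dplyr::mutate(
      coverage_class = ifelse(.data$mean_depth < cov_threshold,
                              "low", "high"),
      cell = paste(.data$length_group, .data$coverage_class, sep = "_")
    )
  cells <- c("g0_499_low", "g0_499_high", "g500_999_low", "g500_999_high",
             "g1000_low", "g1000_high")
  per_bin <- dat %>%
    dplyr::summarise(
      n_windows = dplyr::n(),
      !!!setNames(
        purrr::map(cells, function(cl) {
          rlang::expr(mean(.data$cell == !!cl))
        }),
        paste0("frac_", cells)),
      .by = "bin_id")
  empty <- setdiff(unique(assignments$bin_id), per_bin$bin_id)
  if (length(empty) > 0) {
    per_bin <- dplyr::bind_rows(
      per_bin,
      tibble(bin_id = empty, n_windows = 0L))
  }
  per_bin <- per_bin %>%
    dplyr::mutate(
      frac_fully = .data$frac_g1000_low + .data$frac_g1000_high,
      frac_not_recovered = .data$frac_g0_499_low + .data$frac_g0_499_high
    ) %>%
    dplyr::arrange(dplyr::desc(.data$frac_fully), .data$bin_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
  attr(per_bin, "assembly_label") <- label
  attr(per_bin, "cov_threshold") <- cov_threshold
  class(per_bin) <- c("bin_summary", class(per_bin))
  per_bin
}

#' Count bins by majority recovery status
#'
#' A bin is "mostly fully recovered" when at least `threshold` of its
#' qualifying windows are fully recovered, and "mostly not recovered" when
#' at least `threshold` are not recovered; the two categories are counted
#' independently (a bin can satisfy both when `threshold <= 0.5`). Bins
#' with no qualifying windows count toward neither.
#'
#' @param summaries A `bin_summary` tibble from [summarize_bins()].
#' @param threshold Majority threshold (default 0.5, inclusive).
#' @return A one-row tibble: `n_mostly_fully`, `n_mostly_not_recovered`,
#'   `n_total`.
#' @export
bin_majority_counts <- function(summaries, threshold = 0.5) {
  ok <- summaries$n_windows > 0
  tibble(
    n_mostly_fully = sum(ok & summaries$frac_fully >= threshold,
                         na.rm = TRUE),
    n_mostly_not_recovered = sum(
      ok & summaries$frac_not_recovered >= threshold, na.rm = TRUE),
    n_total = nrow(summaries)
  )
}

#' @export
autoplot.bin_summary <- function(object, ...) {
  cells <- c("g0_499_low", "g0_499_high", "g500_999_low", "g500_999_high",
             "g1000_low", "g1000_high")
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("bin_id", "rank", paste0("frac_", cells))],
    cols = dplyr::all_of(paste0("frac_", cells)),
    names_to = "cell", values_to = "fraction")
  df$cell <- factor(sub("^frac_", "", df$cell), levels = cells)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$fraction,
                                   fill = .data$cell)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "bin rank (by fraction fully recovered)",
                  y = "fraction of windows",
                  fill = "recovery x coverage") +
    ggplot2::theme_minimal()
}
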