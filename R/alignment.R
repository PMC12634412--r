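#' Align reference windows to an assembly with the internal seed-and-extend
#' aligner
#'
#' Finds high-identity local alignments of each window (query) against the
#' contigs of one short-read assembly (subjects). Exact `seed_k`-mer matches
#' on both strands are clustered by diagonal and each cluster is resolved by
#' a banded affine-gap Smith-Waterman (match +1, mismatch -2, a gap of
#' length L costs 5 + 2L). Percent identity is `100 * matches / columns`
#' where columns counts matches + mismatches + gap positions, and only hits
#' strictly above `min_identity` are returned. Minus-strand hits are
#' reported with `s_start > s_end`, query coordinates always forward.
#'
#' A precomputed 12-column tabular alignment file (see
#' [parse_alignment_table()]) can be used instead of this aligner anywhere a
#' hit table is accepted.
#'
#' @param windows A window tibble with `window_id` and `sequence`.
#' @param assembly A contig tibble with `contig_id` and `sequence`.
#' @param label Assembly label attached to every hit (default `"asm"`).
#' @param seed_k Exact seed length (default 15).
#' @param min_identity Strict lower bound on percent identity (default 99.0:
#'   only hits with identity > 99% are kept).
#' @return A tibble of alignment hits: `window_id`, `assembly_label`,
#'   `subject_contig_id`, `pct_identity`, `aln_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `score`.
#' @export
align_windows <- function(windows, assembly, label = "asm", seed_k = 15,
                          min_identity = 99.0) {
  stopifnot(nrow(windows) > 0)
  if (any(nchar(windows$sequence) < seed_k)) {
    stop("all windows must be at least seed_k bases long")
  }
  if (nrow(assembly) == 0) {
    hits <- tibble(window_id = character(), subject_contig_id = character(),
                   pct_identity = numeric(), aln_length = integer(),
                   mismatches = integer(), gap_opens = integer(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(), score = numeric())
  } else {
    hits <- as_tibble(cpp_seed_extend(
      windows$sequence, windows$window_id, assembly$sequence,
      assembly$contig_id, as.integer(seed_k), min_identity,
      1L, -2L, -5L, -2L))
  }
  dplyr::mutate(hits, assembly_label = label,
                .after = "window_id")
}

#' Select the best hit per window and assembly
#'
#' Among hits with identity strictly above `min_identity`, keeps the hit
#' with the greatest alignment length for each (window, assembly) pair.
#' Ties are broken by higher percent identity, then by lexicographically
#' smallest subject contig id, so reruns are deterministic.
#'
#' @param hits A hit tibble (from [align_windows()] or
#'   [parse_alignment_table()] plus an `assembly_label` column).
#' @param min_identity Strict identity threshold (default 99.0).
#' @return A tibble with one row per (window, assembly) that has any
#'   qualifying hit.
#' @export
select_best_hits <- function(hits, min_identity = 99.0) {
  hits %>%
    dplyr::filter(.data$pct_identity > min_identity) %>%
    dplyr::arrange(.data$window_id, .data$assembly_label,
                   dplyr::desc(.data$aln_length),
                   dplyr::desc(.data$pct_identity),
                   .data$subject_contig_id) %>%
    dplyr::distinct(.data$window_id, .data$assembly_label,
                    .keep_all = TRUE)
}

length_group <- function(best_hit_length) {
  dplyr::case_when(
    best_hit_length >= 1000 ~ "g1000",
    best_hit_length >= 500 ~ "g500_999",
    TRUE ~ "g0_499"
  )
}

#' Per-assembly recovery scores for every window
#'
#' Computes percent recovery (100 x best-hit alignment length / window
#' length, capped at 100) for every window and assembly label, filling in
#' zero-recovery rows for windows with no qualifying hit. `assembled_any`
#' flags windows with at least `any_assembled_min` bp assembled (default
#' 100 bp); `fully_assembled` flags 100% recovery. `length_group` buckets
#' the best-hit length into 0-499, 500-999 and >= 1000 bp.
#'
#' @param best_hits Output of [select_best_hits()].
#' @param windows A window index tibble (`window_id`, `end0`, `start0`).
#' @param labels Character vector of assembly labels to score; defaults to
#'   the labels present in `best_hits`.
#' @param any_assembled_min Minimum best-hit length to count a window as
#'   assembled at all (default 100).
#' @return A tibble with one row per window x label: `window_id`,
#'   `assembly_label`, `best_hit_length`, `percent_recovery`,
#'   `assembled_any`, `fully_assembled`, `length_group`.
#' @export
score_recovery <- function(best_hits, windows, labels = NULL,
                           any_assembled_min = 100) {
  if (is.null(labels)) labels <- sort(unique(best_hits$assembly_label))
  stopifnot(length(labels) >= 1)
  wlen <- tibble(window_id = windows$window_id,
                 window_length = windows$end0 - windows$start0)
  grid <- tidyr::expand_grid(window_id = windows$window_id,
                             assembly_label = labels)
  grid %>%
    dplyr::left_join(
      best_hits[, c("window_id", "assembly_label", "aln_length")],
      by = c("window_id", "assembly_label")) %>%
    dplyr::left_join(wlen, by = "window_id") %>%
    dplyr::mutate(
      best_hit_length = dplyr::coalesce(.data$aln_length, 0L),
      percent_recovery = pmin(
        100, 100 * .data$best_hit_length / .data$window_length),
      assembled_any = .data$best_hit_length >= any_assembled_min,
      fully_assembled = .data$percent_recovery == 100,
      length_group = length_group(.data$best_hit_length)
    ) %>%
    dplyr::select(-"aln_length", -"window_length")
}

#' Classify cross-assembler consistency per window
#'
#' For the designated pair of assemblies, a window is consistently
#' assembled (`CA`) when the two best-hit lengths are equal and nonzero,
#' not consistently assembled (`NCA`) when they differ, and `unassembled`
#' when both are zero (so degenerate equality of zeros does not inflate
#' CA; set `zero_equal_ca = TRUE` for strict-equality behaviour).
#' `merged_full` is `TRUE` when the window is fully assembled in every
#' label present in `records`; `recovery_diff` is the absolute difference
#' in percent recovery between the pair.
#'
#' @param records Long recovery tibble from [score_recovery()]; must
#'   contain both labels of `pair`.
#' @param pair Character vector of the two assembly labels to compare.
#' @param zero_equal_ca If `TRUE`, windows unassembled in both count as CA.
#' @return A tibble with one row per window: `window_id`, `consistency`,
#'   `merged_full`, `recovery_diff`.
#' @export
classify_consistency <- function(records, pair = NULL, zero_equal_ca = FALSE) {
  labs <- unique(records$assembly_label)
  if (is.null(pair)) pair <- sort(labs)[1:2]
  if (!all(pair %in% labs)) {
    stop("unknown assembly label(s): ",
         paste(setdiff(pair, labs), collapse = ", "))
  }
  merged <- records %>%
    dplyr::summarise(merged_full = all(.data$fully_assembled),
                     .by = "window_id")
  a <- records[records$assembly_label == pair[1], ]
  b <- records[records$assembly_label == pair[2], ]
  ab <- dplyr::inner_join(
    a[, c("window_id", "best_hit_length", "percent_recovery")],
    b[, c("window_id", "best_hit_length", "percent_recovery")],
    by = "window_id", suffix = c("_a", "_b"))
  ab %>%
    dplyr::mutate(
      consistency = dplyr::case_when(
        .data$best_hit_length_a == 0 & .data$best_hit_length_b == 0 &
          !zero_equal_ca ~ "unassembled",
        .data$best_hit_length_a == .data$best_hit_length_b ~ "CA",
        TRUE ~ "NCA"
      ),
      recovery_diff = abs(.data$percent_recovery_a -
                            .data$percent_recovery_b)
    ) %>%
    dplyr::select("window_id", "consistency", "recovery_diff") %>%
    dplyr::left_join(merged, by = "window_id")
}

#' Histogram of recovery differences between two assemblers
#'
#' Bins the absolute per-window difference in percent recovery between the
#' primary assembler pair. Bins are half-open `[lo, hi)` with the final bin
#' closed; the default edges give a dedicated `[99, 100]` bin for windows
#' recovered by only one assembler.
#'
#' @param consistency Tibble from [classify_consistency()] (needs
#'   `recovery_diff`).
#' @param bin_edges Increasing numeric vector of bin edges (default
#'   `c(0, 10, ..., 90, 99, 100)`).
#' @return A tibble with `bin` (label), `lo`, `hi`, `count`; counts sum to
#'   `nrow(consistency)`.
#' @export
diff_histogram <- function(consistency,
                           bin_edges = c(seq(0, 90, 10), 99, 100)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  lo <- head(bin_edges, -1)
  hi <- tail(bin_edges, -1)
  d <- consistency$recovery_diff
  if (any(d < lo[1] | d > hi[length(hi)])) {
    stop("recovery differences outside the bin range")
  }
  idx <- findInterval(d, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(lo))
  tibble(bin = sprintf("%g-%g", lo, hi), lo = lo, hi = hi, count = counts)
}
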