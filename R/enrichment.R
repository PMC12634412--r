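#' Label genes as fully / not fully assembled
#'
#' Each gene is assigned to the single window containing its midpoint (the
#' earlier window when the midpoint lies in a 500 bp overlap zone), so every
#' gene is counted exactly once. Under `mode = "merged"` a gene is `fully`
#' when its window has 100% recovery in every assembly; under
#' `mode = "per_assembly"` the given `label`'s recovery decides. Genes whose
#' midpoint window is not in the retained reference set (or falls outside
#' all windows) are `unassigned` and excluded from testing.
#'
#' @param genes A gene annotation tibble (see [read_gene_annotations()]).
#' @param records Long recovery tibble from [score_recovery()].
#' @param windows A window index tibble.
#' @param mode `"merged"` or `"per_assembly"`.
#' @param label Assembly label, required for `mode = "per_assembly"`.
#' @param retained Optional character vector of retained window ids (from
#'   [filter_reference_set()]); windows not listed make their genes
#'   `unassigned`.
#' @return A tibble with `gene_id`, `window_id`, `group` (`fully`,
#'   `not_fully`, `unassigned`).
#' @export
assign_gene_groups <- function(genes, records, windows,
                               mode = c("merged", "per_assembly"),
                               label = NULL, retained = NULL) {
  mode <- match.arg(mode)
  unknown <- setdiff(genes$contig_id, windows$contig_id)
  if (length(unknown) > 0) {
    stop("gene(s) on unknown contig: ", paste(head(unknown, 5),
                                              collapse = ", "))
  }
  wfull <- if (mode == "merged") {
    dplyr::summarise(records, fully = all(.data$fully_assembled),
                     .by = "window_id")
  } else {
    if (is.null(label)) stop("mode = 'per_assembly' requires a label")
    if (!label %in% records$assembly_label) {
      stop("unknown assembly label: ", label)
    }
    records %>%
      dplyr::filter(.data$assembly_label == label) %>%
      dplyr::transmute(window_id = .data$window_id,
                       fully = .data$fully_assembled)
  }
  mid <- (genes$start + genes$end) %/% 2L
  win_of <- character(nrow(genes))
  for (cid in unique(genes$contig_id)) {
    gsel <- which(genes$contig_id == cid)
    wsel <- which(windows$contig_id == cid)
    w <- windows[wsel, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mid[gsel], width = 1),
      IRanges::IRanges(start = w$start0 + 1, end = w$end0))
    h <- tibble(gi = S4Vectors::queryHits(hits),
                wi = S4Vectors::subjectHits(hits))
    h$start0 <- w$start0[h$wi]
    h <- h %>%
      dplyr::arrange(.data$gi, .data$start0) %>%
      dplyr::distinct(.data$gi, .keep_all = TRUE)
    win_of[gsel[h$gi]] <- w$window_id[h$wi]
  }
  out <- tibble(gene_id = genes$gene_id, window_id = win_of) %>%
    dplyr::left_join(wfull, by = "window_id")
  out$group <- dplyr::case_when(
    !nzchar(out$window_id) | is.na(out$fully) ~ "unassigned",
    !is.null(retained) & !out$window_id %in% retained ~ "unassigned",
    out$fully ~ "fully",
    TRUE ~ "not_fully"
  )
  out$window_id[!nzchar(out$window_id)] <- NA_character_
  out[, c("gene_id", "window_id", "group")]
}

#' Fisher enrichment of COG categories by assembly status
#'
#' For each observed COG category, builds the 2x2 table of genes in / not
#' in the category crossed with fully / not fully assembled, and applies a
#' two-sided Fisher's exact test. Genes carrying several categories count
#' once in each category they carry; the complement cells count each gene
#' once. P-values are Benjamini-Hochberg adjusted over all tested
#' categories. `direction` reports the side of the sample odds ratio
#' (`a*d / b*c`) for categories significant at `alpha` on the q-value, and
#' `none` otherwise.
#'
#' @param gene_groups Output of [assign_gene_groups()].
#' @param genes The gene annotation tibble (for `cog_categories`).
#' @param alpha Significance level on the q-value for calling a direction
#'   (default 0.05).
#' @return An `enrichment_result` tibble sorted by q-value, with columns
#'   `category`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`,
#'   `direction`.
#' @export
fisher_enrichment <- function(gene_groups, genes, alpha = 0.05) {
  dat <- gene_groups %>%
    dplyr::filter(.data$group %in% c("fully", "not_fully")) %>%
    dplyr::inner_join(genes[, c("gene_id", "cog_categories")], by = "gene_id")
  if (nrow(dat) == 0 || length(unique(dat$group)) == 0) {
    stop("no labeled genes to test")
  }
  n_fully <- sum(dat$group == "fully")
  n_not <- sum(dat$group == "not_fully")
  cats <- dat %>%
    dplyr::mutate(category = strsplit(.data$cog_categories, ";",
                                      fixed = TRUE)) %>%
    tidyr::unnest("category") %>%
    dplyr::filter(nzchar(.data$category))
  observed <- sort(unique(cats$category))
  if (length(observed) == 0) stop("no COG categories observed")
  rows <- purrr::map(observed, function(cg) {
    in_cat <- cats[cats$category == cg, ]
    a <- sum(in_cat$group == "fully")
    c_ <- sum(in_cat$group == "not_fully")
    b <- n_fully - a
    d <- n_not - c_
    ft <- fisher.test(matrix(c(a, c_, b, d), nrow = 2))
    or <- (a * d) / (b * c_)
    tibble(category = cg, a = a, b = b, c = c_, d = d,
           odds_ratio = or, p_value = ft$p.value)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$direction <- dplyr::case_when(
    res$q_value >= alpha | !is.finite(res$odds_ratio) |
      res$odds_ratio == 1 ~ "none",
    res$odds_ratio > 1 ~ "enriched_in_fully",
    TRUE ~ "enriched_in_not_fully"
  )
  res <- dplyr::arrange(res, .data$q_value, .data$category)
  class(res) <- c("enrichment_result", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "n_fully") <- n_fully
  attr(res, "n_not_fully") <- n_not
  res
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_result")
  attr(out, "alpha") <- NULL
  attr(out, "n_fully") <- NULL
  attr(out, "n_not_fully") <- NULL
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$q_value < attr(x, "alpha")),
    alpha = attr(x, "alpha"),
    n_fully = attr(x, "n_fully"),
    n_not_fully = attr(x, "n_not_fully")
  )
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  df$log2_or <- log2(ifelse(df$odds_ratio == 0, NA, df$odds_ratio))
  df$significant <- df$q_value < attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, .data$log2_or),
    y = .data$log2_or, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "COG category",
                  y = "log2 odds ratio (fully vs not fully assembled)",
                  fill = sprintf("q < %g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Fraction of genes fully assembled per gene type
#'
#' Summarizes recovery by gene type (CDS, tRNA, rRNA): for each type, the
#' number of genes labeled fully / not fully assembled and the fraction
#' fully assembled. Types with no labeled genes are reported with zero
#' counts and `NA` fraction.
#'
#' @param genes A gene annotation tibble.
#' @param gene_groups Output of [assign_gene_groups()].
#' @param types Gene types to report (default `CDS`, `tRNA`, `rRNA`).
#' @return A tibble with `gene_type`, `n_fully`, `n_not_fully`,
#'   `fraction_fully`.
#' @export
gene_type_recovery <- function(genes, gene_groups,
                               types = c("CDS", "tRNA", "rRNA")) {
  dat <- gene_groups %>%
    dplyr::inner_join(genes[, c("gene_id", "gene_type")], by = "gene_id") %>%
    dplyr::filter(.data$group %in% c("fully", "not_fully"))
  out <- purrr::map(types, function(tp) {
    sub <- dat[dat$gene_type == tp, ]
    nf <- sum(sub$group == "fully")
    nn <- sum(sub$group == "not_fully")
    tibble(gene_type = tp, n_fully = nf, n_not_fully = nn,
           fraction_fully = if (nf + nn > 0) nf / (nf + nn) else NA_real_)
  })
  dplyr::bind_rows(out)
}
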