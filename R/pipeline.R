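#' Run the full window-recovery pipeline
#'
#' Executes the stages in order: windowing of the reference contigs,
#' coverage summary and breadth filter, alignment of windows to each
#' assembly and recovery scoring, cross-assembler consistency, recovery
#' difference histogram, SNP counts and CA-vs-NCA comparison, per-window
#' de Bruijn graph metrics (when reads and placements are supplied), gene
#' enrichment (when annotations are supplied), and the bin report (when bin
#' assignments are supplied). Each stage logs a line with record counts;
#' reruns on identical inputs are byte-identical.
#'
#' @param reference_fasta Path to the long-read reference contig FASTA.
#' @param assembly_fastas Named character vector (>= 2 entries) of
#'   assembly FASTA paths; names are the assembly labels.
#' @param depth_tsv Path to the 3-column per-base depth table.
#' @param vcf,annotations_tsv,bins_tsv,reads_fastq,placements_tsv Optional
#'   paths enabling the SNP, enrichment, bin and graph stages.
#' @param hits_tsv Optional named character vector of precomputed
#'   12-column alignment tables (one per assembly label), bypassing the
#'   internal aligner.
#' @param out_dir Optional directory; when given, every stage writes its
#'   TSV there.
#' @param width,step Window geometry (defaults 1000 / 500).
#' @param min_breadth,min_depth Reference-set retention filter (defaults
#'   0.8 / 1).
#' @param min_identity Strict identity threshold for alignment hits
#'   (default 99).
#' @param any_assembled_min Minimum best-hit length to count a window as
#'   assembled (default 100).
#' @param k,min_count,max_dist De Bruijn graph parameters (defaults 31, 2,
#'   3; see [window_graph_metrics()] for the abundance cutoff rationale).
#' @param cov_threshold,min_cov Bin-report coverage parameters (defaults
#'   10, 1).
#' @param primary_pair The two assembly labels compared for CA/NCA
#'   (default: first two of `assembly_fastas`).
#' @param enrich_mode `"merged"` or `"per_assembly"` for gene labels.
#' @param enrich_label Label used when `enrich_mode = "per_assembly"`.
#' @param verbose Log stage progress to standard error (default TRUE).
#' @return A named list of result tibbles: `windows`, `coverage`,
#'   `retained`, `recovery`, `consistency`, `diff_hist`, and when inputs
#'   allow `snp_counts`, `snp_test`, `graph_metrics`, `gene_groups`,
#'   `enrichment`, `gene_types`, `bin_summary`, `bin_counts`.
#' @export
run_pipeline <- function(reference_fasta, assembly_fastas, depth_tsv,
                         vcf = NULL, annotations_tsv = NULL,
                         bins_tsv = NULL, reads_fastq = NULL,
                         placements_tsv = NULL, hits_tsv = NULL,
                         out_dir = NULL, width = 1000, step = 500,
                         min_breadth = 0.8, min_depth = 1,
                         min_identity = 99, any_assembled_min = 100,
                         k = 31, min_count = 2, max_dist = 3,
                         cov_threshold = 10, min_cov = 1,
                         primary_pair = NULL,
                         enrich_mode = c("merged", "per_assembly"),
                         enrich_label = NULL, verbose = TRUE) {
  enrich_mode <- match.arg(enrich_mode)
  say <- function(...) if (verbose) message(sprintf(...))
  for (p in c(reference_fasta, unname(assembly_fastas), depth_tsv, vcf,
              annotations_tsv, bins_tsv, reads_fastq, placements_tsv,
              unname(hits_tsv))) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (is.null(names(assembly_fastas)) || any(!nzchar(names(assembly_fastas)))) {
    stop("assembly_fastas must be a named vector of paths")
  }
  labels <- names(assembly_fastas)
  if (is.null(primary_pair)) primary_pair <- labels[1:2]
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_hashed_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }

  contigs <- read_contigs(reference_fasta)
  windows <- make_windows(contigs, width = width, step = step)
  say("windows: %d windows from %d contigs", nrow(windows), nrow(contigs))
  emit(windows[, c("window_id", "contig_id", "start0", "end0")], "windows")

  depth <- parse_depth_table(depth_tsv)
  coverage <- coverage_summary(
    depth, windows, min_depth = min_depth, min_breadth = min_breadth,
    cov_threshold = cov_threshold,
    contig_lengths = setNames(contigs$length, contigs$contig_id))
  retained <- filter_reference_set(coverage, min_breadth = min_breadth)
  say("coverage: %d / %d windows retained (breadth >= %g)",
      length(retained), nrow(windows), min_breadth)
  emit(coverage, "coverage")
  wret <- windows[windows$window_id %in% retained, ]

  all_hits <- purrr::map(labels, function(lab) {
    if (!is.null(hits_tsv) && lab %in% names(hits_tsv)) {
      h <- parse_alignment_table(hits_tsv[[lab]])
      h$assembly_label <- lab
      h
    } else {
      asm <- read_contigs(assembly_fastas[[lab]])
      align_windows(wret, asm, label = lab, min_identity = min_identity)
    }
  }) %>% dplyr::bind_rows()
  best <- select_best_hits(all_hits, min_identity = min_identity)
  recovery <- score_recovery(best, wret, labels = labels,
                             any_assembled_min = any_assembled_min)
  say("recovery: %d hits -> %d best, %d window x assembly records",
      nrow(all_hits), nrow(best), nrow(recovery))
  emit(recovery, "recovery")

  consistency <- classify_consistency(recovery, pair = primary_pair)
  dh <- diff_histogram(consistency)
  say("consistency: %d CA, %d NCA, %d unassembled",
      sum(consistency$consistency == "CA"),
      sum(consistency$consistency == "NCA"),
      sum(consistency$consistency == "unassembled"))
  emit(consistency, "consistency")
  emit(dh, "diff_hist")

  out <- list(windows = windows, coverage = coverage, retained = retained,
              recovery = recovery, consistency = consistency,
              diff_hist = dh)

  if (!is.null(vcf)) {
    variants <- read_vcf_snps(vcf)
    snp_counts <- count_snps(variants, wret)
    cc <- dplyr::inner_join(snp_counts, consistency, by = "window_id")
    ca <- cc$snp_count[cc$consistency == "CA"]
    nca <- cc$snp_count[cc$consistency == "NCA"]
    out$snp_counts <- snp_counts
    if (length(ca) > 0 && length(nca) > 0) {
      out$snp_test <- snp_group_test(ca, nca)
    }
    say("snps: %d variant records counted over %d windows",
        nrow(variants), nrow(snp_counts))
    emit(snp_counts, "snp_counts")
  }

  if (!is.null(reads_fastq) && !is.null(placements_tsv)) {
    reads <- read_reads_fastq(reads_fastq)
    placements <- read_placements(placements_tsv)
    gm <- window_graph_metrics(reads, placements, wret, k = k,
                               min_count = min_count, max_dist = max_dist)
    out$graph_metrics <- gm
    say("graphs: metrics for %d windows (k = %d)", nrow(gm), k)
    emit(gm, "graph_metrics")
  }

  if (!is.null(annotations_tsv)) {
    genes <- read_gene_annotations(annotations_tsv)
    gene_groups <- assign_gene_groups(
      genes, recovery, windows, mode = enrich_mode, label = enrich_label,
      retained = retained)
    enr <- fisher_enrichment(gene_groups, genes)
    gt <- gene_type_recovery(genes, gene_groups)
    out$gene_groups <- gene_groups
    out$enrichment <- enr
    out$gene_types <- gt
    say("enrichment: %d categories tested, %d significant",
        nrow(enr), sum(enr$q_value < attr(enr, "alpha")))
    emit(tidy(enr), "enrichment")
    emit(gt, "gene_types")
  }

  if (!is.null(bins_tsv)) {
    assignments <- read_bin_assignments(bins_tsv)
    bs <- summarize_bins(assignments, recovery, coverage, windows,
                         label = primary_pair[1],
                         cov_threshold = cov_threshold, min_cov = min_cov)
    bc <- bin_majority_counts(bs)
    out$bin_summary <- bs
    out$bin_counts <- bc
    say("bins: %d bins, %d mostly fully recovered, %d mostly not recovered",
        bc$n_total, bc$n_mostly_fully, bc$n_mostly_not_recovered)
    emit(as_tibble(bs), "bin_summary")
    emit(bc, "bin_counts")
  }

  out
}
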