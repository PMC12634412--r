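toy_windows <- function() {
  tibble::tibble(
    window_id = c("c1:1-1000", "c1:501-1500", "c1:1001-2000"),
    contig_id = "c1", start0 = c(0L, 500L, 1000L),
    end0 = c(1000L, 1500L, 2000L))
}

toy_records <- function(full_a = c(TRUE, FALSE, TRUE),
                        full_b = c(TRUE, FALSE, FALSE)) {
  w <- toy_windows()
  tibble::tibble(
    window_id = rep(w$window_id, 2),
    assembly_label = rep(c("a", "b"), each = 3),
    best_hit_length = 1000L,
    percent_recovery = ifelse(c(full_a, full_b), 100, 50),
    fully_assembled = c(full_a, full_b))
}

test_that("genes map to the window containing their midpoint, earlier
           window on ties", {
  w <- toy_windows()
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    contig_id = "c1",
    start = c(100L, 650L, 1900L),
    end = c(400L, 750L, 1990L),
    strand = "+", gene_type = "CDS", cog_categories = "J")
  gg <- assign_gene_groups(genes, toy_records(), w, mode = "merged")
  # g1 midpoint 250: only window 1. g2 midpoint 700: windows 1 and 2 ->
  # earlier window 1. g3 midpoint 1945: only window 3.
  expect_identical(gg$window_id, c("c1:1-1000", "c1:1-1000", "c1:1001-2000"))
  # merged labels: window 1 fully in both -> fully; window 3 only in a
  expect_identical(gg$group, c("fully", "fully", "not_fully"))
  # per-assembly view of the discordant window
  gg_a <- assign_gene_groups(genes, toy_records(), w,
                             mode = "per_assembly", label = "a")
  expect_identical(gg_a$group[3], "fully")
  # retained set exclusion
  gg_r <- assign_gene_groups(genes, toy_records(), w, mode = "merged",
                             retained = c("c1:1-1000"))
  expect_identical(gg_r$group, c("fully", "fully", "unassigned"))
  # unknown contig errors
  bad <- dplyr::mutate(genes, contig_id = "c9")
  expect_error(assign_gene_groups(bad, toy_records(), w), "unknown contig")
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  # frozen example: 2x2 table (2,8 / 8,2)
  expect_equal(round(fisher_enum_p(2, 8, 8, 2), 3), 0.023)
  expect_equal(stats::fisher.test(matrix(c(2, 8, 8, 2), 2))$p.value,
               fisher_enum_p(2, 8, 8, 2), tolerance = 1e-9)
  # balanced table
  expect_equal(stats::fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # 100 random tables with margins <= 30
  set.seed(41)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + c_ == 0 || b + d == 0 || a + b == 0 || c_ + d == 0) next
    expect_equal(
      stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
      fisher_enum_p(a, b, c_, d), tolerance = 1e-9,
      info = paste(a, b, c_, d))
  }
})

test_that("BH adjustment reproduces the step-up rule and is monotone", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(42)
  p <- sort(runif(20))
  q <- stats::p.adjust(p, "BH")
  expect_true(all(diff(q) >= 0))
  # manual step-up: q_i = min_{j >= i} p_j * m / j
  m <- length(p)
  manual <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(q, pmin(manual, 1))
})

test_that("fisher_enrichment builds correct tables and directions", {
  # 20 genes over 2 windows: window 1 fully, window 3 not (merged)
  w <- toy_windows()
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    contig_id = "c1",
    start = rep(c(100L, 1900L), each = 10),
    end = rep(c(300L, 1950L), each = 10),
    strand = "+", gene_type = "CDS",
    cog_categories = c(rep("J", 8), rep("X", 2), rep("X", 7), rep("J;K", 3)))
  gg <- assign_gene_groups(genes, toy_records(), w, mode = "merged")
  enr <- fisher_enrichment(gg, genes)
  x <- enr[enr$category == "X", ]
  expect_equal(x$a + x$b, 10)        # fully-assembled margin
  expect_equal(x$c + x$d, 10)
  expect_equal(x$a, 2)               # X genes in the fully window
  expect_equal(x$c, 7)
  ft <- stats::fisher.test(matrix(c(2, 7, 8, 3), 2))
  expect_equal(x$p_value, ft$p.value, tolerance = 1e-12)
  # q-values are BH over the tested categories
  expect_equal(enr$q_value, stats::p.adjust(enr$p_value, "BH"),
               tolerance = 1e-12)
  # multi-category genes count once per carried letter
  k <- enr[enr$category == "K", ]
  expect_equal(k$a + k$c, 3)
  # glance/tidy interface
  gl <- glance(enr)
  expect_equal(gl$n_categories, nrow(enr))
  expect_s3_class(tidy(enr), "tbl_df")
  expect_false(inherits(tidy(enr), "enrichment_result"))
})

test_that("gene-type recovery fractions and absent types", {
  w <- toy_windows()
  genes <- tibble::tibble(
    gene_id = sprintf("t%02d", 1:10),
    contig_id = "c1",
    start = c(rep(100L, 4), rep(1900L, 6)),
    end = c(rep(200L, 4), rep(1950L, 6)),
    strand = "+",
    gene_type = "tRNA",
    cog_categories = "")
  gg <- assign_gene_groups(genes, toy_records(), w, mode = "merged")
  gt <- gene_type_recovery(genes, gg)
  expect_equal(gt$fraction_fully[gt$gene_type == "tRNA"], 0.4)
  expect_equal(gt$n_fully[gt$gene_type == "rRNA"], 0)
  expect_true(is.na(gt$fraction_fully[gt$gene_type == "rRNA"]))
  # all genes fully assembled
  all_full <- toy_records(full_a = c(TRUE, TRUE, TRUE),
                          full_b = c(TRUE, TRUE, TRUE))
  gg2 <- assign_gene_groups(genes, all_full, w, mode = "merged")
  gt2 <- gene_type_recovery(genes, gg2)
  expect_equal(gt2$fraction_fully[gt2$gene_type == "tRNA"], 1)
})
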