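one_window <- function(seq) tibble::tibble(window_id = "w1", sequence = seq)
one_subject <- function(seq, id = "s1") {
  tibble::tibble(contig_id = id, sequence = seq)
}

test_that("exact, lightly mutated and heavily mutated subjects behave as
           the identity threshold dictates", {
  set.seed(21)
  w <- one_window(rdna(1000))
  # exact substring
  h <- align_windows(w, one_subject(paste0(rdna(150), w$sequence, rdna(90))))
  expect_equal(nrow(h), 1)
  expect_equal(h$aln_length, 1000L)
  expect_equal(h$pct_identity, 100)
  # two substitutions: still above the 99% threshold
  s2 <- mutate_seq(w$sequence, n_sub = 2)
  h2 <- align_windows(w, one_subject(s2))
  best2 <- select_best_hits(h2)
  o2 <- sw_oracle(w$sequence, s2)
  expect_equal(best2$aln_length, o2$columns)
  expect_equal(best2$pct_identity, o2$identity, tolerance = 1e-9)
  expect_gt(best2$pct_identity, 99)
  # fifteen spread-out substitutions: no (near-)full-length hit survives
  set.seed(22)
  chars <- strsplit(w$sequence, "")[[1]]
  pos <- round(seq(30, 970, length.out = 15))
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  s15 <- paste(chars, collapse = "")
  h15 <- align_windows(w, one_subject(s15))
  expect_true(nrow(h15) == 0 || max(h15$aln_length) < 1000)
})

test_that("best hits match a full Smith-Waterman oracle on random mutated
           pairs", {
  set.seed(23)
  for (i in 1:40) {
    q <- rdna(1000)
    subj <- mutate_seq(paste0(rdna(sample(0:100, 1)), q,
                              rdna(sample(0:100, 1))),
                       n_sub = sample(0:10, 1), n_indel = sample(0:2, 1))
    h <- align_windows(one_window(q), one_subject(subj), min_identity = 95)
    o <- sw_oracle(q, subj)
    best <- select_best_hits(h, min_identity = 95)
    expect_equal(best$score, o$score, info = i)
    expect_equal(best$aln_length, o$columns, info = i)
    expect_equal(best$pct_identity, o$identity, tolerance = 1e-9, info = i)
  }
})

test_that("recovery is invariant to subject strand", {
  set.seed(24)
  w <- one_window(rdna(1000))
  subj <- mutate_seq(paste0(rdna(80), w$sequence, rdna(40)), n_sub = 3)
  fwd <- select_best_hits(align_windows(w, one_subject(subj)))
  rev <- select_best_hits(align_windows(w, one_subject(revcomp_chr(subj))))
  expect_equal(fwd$aln_length, rev$aln_length)
  expect_equal(fwd$pct_identity, rev$pct_identity, tolerance = 1e-9)
  expect_true(rev$s_start > rev$s_end)  # minus strand signalled
  expect_true(fwd$s_start < fwd$s_end)
})

test_that("best-hit selection applies the strict threshold and tie breaks", {
  hits <- tibble::tibble(
    window_id = "w1", assembly_label = "a",
    subject_contig_id = c("c3", "c2", "c1"),
    pct_identity = c(100, 99.5, 99.9),
    aln_length = c(400L, 850L, 850L),
    score = 0)
  best <- select_best_hits(hits)
  expect_identical(best$subject_contig_id, "c1")  # length tie -> identity
  expect_equal(best$aln_length, 850L)
  # identity exactly 99.0 is excluded (strict > 99)
  at99 <- dplyr::mutate(hits[1, ], pct_identity = 99.0)
  expect_equal(nrow(select_best_hits(at99)), 0)
  # full tie resolved by smallest subject id
  tie <- dplyr::mutate(hits, pct_identity = 99.9, aln_length = 850L)
  expect_identical(select_best_hits(tie)$subject_contig_id, "c1")
  expect_equal(nrow(select_best_hits(hits[0, ])), 0)
})

test_that("recovery scoring arithmetic, flags and length groups", {
  w <- tibble::tibble(window_id = c("w1", "w2", "w3"),
                      contig_id = "c", start0 = c(0, 500, 1000),
                      end0 = c(1000, 1500, 2000))
  best <- tibble::tibble(
    window_id = c("w1", "w2"), assembly_label = "a",
    aln_length = c(1000L, 537L))
  rec <- score_recovery(best, w, labels = "a")
  expect_equal(rec$percent_recovery, c(100, 53.7, 0))
  expect_equal(rec$best_hit_length, c(1000L, 537L, 0L))
  expect_identical(rec$length_group, c("g1000", "g500_999", "g0_499"))
  expect_identical(rec$fully_assembled, c(TRUE, FALSE, FALSE))
  expect_identical(rec$assembled_any, c(TRUE, TRUE, FALSE))
})

test_that("consistency classification is symmetric with an unassembled
           class", {
  w <- tibble::tibble(window_id = c("w1", "w2", "w3"),
                      contig_id = "c", start0 = c(0, 500, 1000),
                      end0 = c(1000, 1500, 2000))
  best <- tibble::tibble(
    window_id = c("w1", "w1", "w2", "w2"),
    assembly_label = c("a", "b", "a", "b"),
    aln_length = c(800L, 800L, 800L, 1000L))
  rec <- score_recovery(best, w, labels = c("a", "b"))
  cons <- classify_consistency(rec, pair = c("a", "b"))
  expect_identical(cons$consistency[match(c("w1", "w2", "w3"),
                                          cons$window_id)],
                   c("CA", "NCA", "unassembled"))
  flipped <- classify_consistency(rec, pair = c("b", "a"))
  expect_identical(cons$consistency[order(cons$window_id)],
                   flipped$consistency[order(flipped$window_id)])
  strict <- classify_consistency(rec, pair = c("a", "b"),
                                 zero_equal_ca = TRUE)
  expect_identical(strict$consistency[strict$window_id == "w3"], "CA")
  expect_error(classify_consistency(rec, pair = c("a", "nope")), "unknown")
})

test_that("difference histogram bins are half-open with a closed last bin", {
  cons <- tibble::tibble(recovery_diff = c(0, 5, 100, 99, 98.9, 10))
  dh <- diff_histogram(cons)
  expect_equal(sum(dh$count), nrow(cons))
  expect_equal(dh$count[dh$bin == "0-10"], 2)    # 0 and 5
  expect_equal(dh$count[dh$bin == "10-20"], 1)   # 10 goes right
  expect_equal(dh$count[dh$bin == "90-99"], 1)   # 98.9
  expect_equal(dh$count[dh$bin == "99-100"], 2)  # 99 and 100
  all0 <- diff_histogram(tibble::tibble(recovery_diff = rep(0, 7)))
  expect_equal(all0$count[1], 7)
  expect_error(diff_histogram(cons, bin_edges = c(0, 50, 40, 100)),
               "increasing")
})
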