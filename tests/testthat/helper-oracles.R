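# Independent oracles and small fixture builders shared across the suite.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Naive window-start enumerator: all p with p + width <= L and p = i * step.
naive_window_starts <- function(L, width, step) {
  p <- seq(0, max(0, L), by = step)
  p[p + width <= L]
}

# Apply point substitutions (to a different base) and up to a few 1-3 bp
# indels to a sequence; returns the mutated string.
mutate_seq <- function(seq, n_sub = 0, n_indel = 0) {
  chars <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample.int(length(chars), n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  }
  if (n_indel > 0) {
    for (i in seq_len(n_indel)) {
      p <- sample(seq(10, length(chars) - 10), 1)
      w <- sample(1:3, 1)
      if (runif(1) < 0.5) {
        chars <- append(chars, sample(c("A", "C", "G", "T"), w, TRUE), after = p)
      } else {
        chars <- chars[-(p:(p + w - 1))]
      }
    }
  }
  paste(chars, collapse = "")
}

# Full Smith-Waterman oracle via Biostrings::pairwiseAlignment with the
# aligner's scoring (match +1, mismatch -2, gap of length L costs 5 + 2L).
# Tries both subject strands and returns the stats of the better one.
sw_oracle <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE)
  best <- NULL
  for (s in c(subject, revcomp_chr(subject))) {
    pa <- Biostrings::pairwiseAlignment(
      query, s, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    ni <- Biostrings::nindel(pa)
    cols <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
      sum(Biostrings::insertion(ni)[, "WidthSum"]) +
      sum(Biostrings::deletion(ni)[, "WidthSum"])
    cand <- list(score = Biostrings::score(pa),
                 columns = cols,
                 matches = Biostrings::nmatch(pa),
                 identity = 100 * Biostrings::nmatch(pa) / cols)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# Naive canonical k-mer counter in plain R (string based).
naive_kmer_table <- function(seqs, k) {
  km <- unlist(lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    starts <- seq_len(nchar(s) - k + 1)
    substring(s, starts, starts + k - 1)
  }))
  km <- km[!grepl("[^ACGT]", km)]
  canon <- pmin(km, revcomp_chr(km))
  tab <- table(canon)
  tibble::tibble(kmer = names(tab), count = as.integer(tab))
}

# Exhaustive two-sided Fisher p-value by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (fisher.test's rule).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c          # genes in category
  n <- b + d          # genes not in category
  kk <- a + b         # fully assembled
  x <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(x, m, n, kk)
  p_obs <- stats::dhyper(a, m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by explicit enumeration of all
# C(n1 + n2, n1) group assignments of the observed values.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  n <- length(vals)
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small deterministic clean community used by several end-to-end tests.
clean_community <- function(seed = 42, depth = 30, genome_length = 20000,
                            n_genomes = 2) {
  cfg <- community_config(
    n_genomes = n_genomes, genome_length = genome_length,
    islands_per_genome = 0, background_snp_density = 0,
    error_rate = 0, abundance_sigma = 0,
    total_bases = depth * n_genomes * genome_length, seed = seed)
  simulate_community(cfg)
}
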