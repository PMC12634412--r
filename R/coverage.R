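#' Per-window depth tracks from a per-base depth table
#'
#' Projects a 3-column depth table (name, 1-based position, depth) onto the
#' window index. Reference names may be window ids or contig ids; both
#' dialects are accepted and may be mixed. Positions absent from the table
#' get depth 0. Every window in the index yields a track.
#'
#' @param depth_records A tibble with `name`, `pos`, `depth` (e.g. from
#'   [parse_depth_table()]).
#' @param windows A window index tibble (`window_id`, `contig_id`, `start0`,
#'   `end0`).
#' @param contig_lengths Optional named vector of contig lengths, used to
#'   validate contig-level positions; window-level positions are always
#'   validated against the window length.
#' @return A tibble with `window_id` and a `depths` list-column of integer
#'   vectors (one entry per window position).
#' @export
window_depth <- function(depth_records, windows, contig_lengths = NULL) {
  stopifnot(all(c("name", "pos", "depth") %in% names(depth_records)))
  wlen <- windows$end0 - windows$start0
  is_window <- depth_records$name %in% windows$window_id
  is_contig <- !is_window & depth_records$name %in% windows$contig_id
  unknown <- !is_window & !is_contig
  if (any(unknown)) {
    stop("depth record name matches no window or contig: ",
         depth_records$name[which(unknown)[1]])
  }
  wrec <- depth_records[is_window, , drop = FALSE]
  if (nrow(wrec) > 0) {
    maxlen <- wlen[match(wrec$name, windows$window_id)]
    bad <- wrec$pos > maxlen
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("depth record (%s, pos %d) beyond window length %d",
                   wrec$name[i], wrec$pos[i], maxlen[i]))
    }
  }
  crec <- depth_records[is_contig, , drop = FALSE]
  if (!is.null(contig_lengths) && nrow(crec) > 0) {
    bad <- crec$pos > contig_lengths[crec$name]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("depth record (%s, pos %d) beyond contig length %d",
                   crec$name[i], crec$pos[i],
                   as.integer(contig_lengths[crec$name[i]])))
    }
  }
  crec_split <- split(crec[c("pos", "depth")], crec$name)
  wrec_split <- split(wrec[c("pos", "depth")], wrec$name)
  tracks <- purrr::pmap(
    list(windows$window_id, windows$contig_id, windows$start0, wlen),
    function(wid, cid, s0, len) {
      d <- integer(len)
      wr <- wrec_split[[wid]]
      if (!is.null(wr)) d[wr$pos] <- d[wr$pos] + wr$depth
      cr <- crec_split[[cid]]
      if (!is.null(cr)) {
        sel <- cr$pos > s0 & cr$pos <= s0 + len
        if (any(sel)) {
          d[cr$pos[sel] - s0] <- d[cr$pos[sel] - s0] + cr$depth[sel]
        }
      }
      d
    }
  )
  tibble(window_id = windows$window_id, depths = tracks)
}

#' Per-window coverage summaries
#'
#' Computes mean depth and breadth of coverage (the fraction of positions
#' covered at `min_depth` or more) for every window, flags windows passing
#' the breadth retention filter, and assigns the low/high coverage class
#' used by the bin report.
#'
#' @inheritParams window_depth
#' @param min_depth Minimum per-base depth for a position to count as
#'   covered (default 1).
#' @param min_breadth Minimum breadth for a window to pass the retention
#'   filter (default 0.8, i.e. at least 1x coverage over 80% of the window).
#' @param cov_threshold Mean depth at or above which a window is classed
#'   `high` coverage (default 10).
#' @return A tibble with `window_id`, `mean_depth`, `breadth`,
#'   `pass_filter`, `coverage_class`.
#' @export
coverage_summary <- function(depth_records, windows, min_depth = 1,
                             min_breadth = 0.8, cov_threshold = 10,
                             contig_lengths = NULL) {
  tracks <- window_depth(depth_records, windows, contig_lengths)
  mean_depth <- vapply(tracks$depths, function(d) sum(d) / length(d), 0)
  breadth <- vapply(tracks$depths,
                    function(d) mean(d >= min_depth), 0)
  tibble(
    window_id = tracks$window_id,
    mean_depth = mean_depth,
    breadth = breadth,
    pass_filter = breadth >= min_breadth,
    coverage_class = ifelse(mean_depth < cov_threshold, "low", "high")
  )
}

#' Apply the breadth-of-coverage retention filter
#'
#' A window is retained when its breadth of coverage is at least
#' `min_breadth` (default: depth >= 1 over at least 80% of the window,
#' i.e. 800 bp of a 1 kb window). The retained set is the reference
#' universe for all downstream scoring.
#'
#' @param summaries A coverage summary tibble from [coverage_summary()].
#' @param min_breadth Retention threshold on breadth (default 0.8).
#' @return A character vector of retained `window_id`s.
#' @export
filter_reference_set <- function(summaries, min_breadth = 0.8) {
  summaries$window_id[summaries$breadth >= min_breadth]
}

#' Count SNPs per window from VCF records
#'
#' Only records with a single-base REF and at least one single-base ALT
#' allele count as SNPs. Variant positions are contig-level and 1-based; a
#' SNP falling in the overlap zone of two sliding windows increments both,
#' since each window is scored independently. Records with quality below
#' `min_qual` are skipped (records with missing quality are kept).
#'
#' @param variants A tibble with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `qual` (e.g. from [read_vcf_snps()]).
#' @param windows A window index tibble.
#' @param min_qual Minimum QUAL to count a record (default 0: no filter).
#' @return A tibble with `window_id` and `snp_count` (0 for windows with no
#'   SNP).
#' @export
count_snps <- function(variants, windows, min_qual = 0) {
  counts <- integer(nrow(windows))
  if (nrow(variants) > 0) {
    alt_list <- strsplit(variants$alt, ",", fixed = TRUE)
    is_snp <- nchar(variants$ref) == 1 &
      vapply(alt_list, function(a) any(nchar(a) == 1 & a %in%
                                         c("A", "C", "G", "T")), TRUE)
    if ("qual" %in% names(variants)) {
      is_snp <- is_snp & (is.na(variants$qual) | variants$qual >= min_qual)
    }
    snps <- variants[is_snp, , drop = FALSE]
    for (cid in unique(snps$chrom)) {
      widx <- which(windows$contig_id == cid)
      if (length(widx) == 0) next
      s <- snps[snps$chrom == cid, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = s$pos, width = 1),
        IRanges::IRanges(start = windows$start0[widx] + 1,
                         end = windows$end0[widx]))
      tab <- table(S4Vectors::subjectHits(hits))
      counts[widx[as.integer(names(tab))]] <-
        counts[widx[as.integer(names(tab))]] + as.integer(tab)
    }
  }
  tibble(window_id = windows$window_id, snp_count = counts)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test used to compare SNP counts (and graph metrics) between
#' window groups. When both groups have fewer than 20 observations the
#' two-sided p-value is computed from the exact conditional distribution of
#' U given the observed (mid-)ranks, so ties are handled exactly; otherwise
#' a normal approximation with tie correction (and no continuity
#' correction) is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A one-row tibble with `statistic` (U for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @export
mw_u_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 < 20 && n2 < 20
  if (exact) {
    p <- mw_exact_p(r, n1)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble(statistic = u, p_value = p, method = method, n_x = n1, n_y = n2)
}

# Exact two-sided p for the Mann-Whitney U under the conditional
# distribution given the observed midranks: a generating-function DP counts
# the subsets of size n1 by doubled rank sum.
mw_exact_p <- function(r, n1) {
  d <- as.integer(round(2 * r))  # doubled midranks are integers
  n <- length(d)
  smax <- sum(d)
  # f[j + 1, s + 1] = number of size-j subsets with doubled rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (i in seq_len(n)) {
    jmax <- min(i, n1)
    for (j in jmax:1) {
      shift <- d[i]
      src <- f[j, seq_len(smax + 1 - shift)]
      idx <- (shift + 1):(smax + 1)
      f[j + 1, idx] <- f[j + 1, idx] + src
    }
  }
  counts <- f[n1 + 1, ]
  s_vals <- 0:smax
  u_vals <- s_vals / 2 - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  r1_obs <- sum(r[seq_len(n1)])
  u_obs <- r1_obs - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - mu)
  sel <- abs(u_vals - mu) >= dev_obs - 1e-9
  sum(counts[sel]) / choose(n, n1)
}

#' Compare SNP counts between consistency classes
#'
#' Tests whether windows that are not consistently assembled (NCA) carry
#' more SNPs than consistently assembled (CA) windows, using the two-sided
#' Mann-Whitney U test of [mw_u_test()].
#'
#' @param ca_counts,nca_counts Integer vectors of per-window SNP counts for
#'   the CA and NCA groups; both must be non-empty.
#' @return A one-row tibble with `statistic` (U for the CA group),
#'   `p_value`, `median_diff` (`median(nca) - median(ca)`), `method`,
#'   `n_ca`, `n_nca`.
#' @export
snp_group_test <- function(ca_counts, nca_counts) {
  res <- mw_u_test(ca_counts, nca_counts)
  tibble(
    statistic = res$statistic,
    p_value = res$p_value,
    median_diff = median(nca_counts) - median(ca_counts),
    method = res$method,
    n_ca = res$n_x,
    n_nca = res$n_y
  )
}
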