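#' Configuration for a synthetic community
#'
#' Describes a community of uniform-random genomes with lognormal
#' abundances, each carrying a major and a minor strain haplotype. Minor
#' haplotype substitutions are planted at `island_snp_density` per bp
#' inside a configurable number of "diversity islands" and at
#' `background_snp_density` elsewhere, emulating localized strain
#' heterogeneity (e.g. integrated viruses or defense islands). The emitted
#' reference contigs stand in for a long-read assembly: each is the major
#' haplotype trimmed by `contig_margin` bp at both ends, so that window
#' scoring is not confounded by sequencing edge effects at the true genome
#' ends.
#'
#' Genes tile the reference region with a fixed length and alternating
#' strand; a fraction `mobile_cog_fraction_in_islands` of island genes
#' carry the mobilome category `X`, while all other genes draw uniformly
#' from a non-`X` alphabet. A few tRNA and rRNA genes per genome are placed
#' uniformly. Ground-truth bins are the genome identities.
#'
#' @param n_genomes Number of genomes (default 3).
#' @param genome_length Genome length in bp (default 50000).
#' @param abundance_mu,abundance_sigma Parameters of the lognormal genome
#'   abundance distribution (defaults 0 and 0.5).
#' @param islands_per_genome Diversity islands per island-carrying genome
#'   (default 1).
#' @param n_island_genomes Number of genomes (the first ones) that carry
#'   islands; the rest are island-free (default: all).
#' @param island_length Island length in bp (default 5000).
#' @param island_snp_density Minor-haplotype substitutions per bp inside
#'   islands (default 0.01).
#' @param background_snp_density Substitutions per bp outside islands
#'   (default 0).
#' @param minor_haplotype_freq Frequency of the minor haplotype in the
#'   read pool, in (0, 0.5] (default 0.3).
#' @param read_length Read length in bp (default 150; reads are single-end).
#' @param error_rate Per-base substitution error probability (default
#'   0.001).
#' @param total_bases Total sequencing in bp (default 30x the summed genome
#'   length).
#' @param mobile_cog_fraction_in_islands Fraction of island genes assigned
#'   COG category `X` (default 0.8).
#' @param contig_margin Bases trimmed from each genome end to form the
#'   reference contig (default 200).
#' @param gene_length CDS tiling length in bp (default 900).
#' @param trna_per_genome,rrna_per_genome Count of tRNA (76 bp) and rRNA
#'   (1500 bp) genes placed per genome (defaults 4 and 1).
#' @param seed Integer seed; fully determines all outputs.
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes = 3, genome_length = 50000,
                             abundance_mu = 0, abundance_sigma = 0.5,
                             islands_per_genome = 1, island_length = 5000,
                             n_island_genomes = n_genomes,
                             island_snp_density = 0.01,
                             background_snp_density = 0,
                             minor_haplotype_freq = 0.3,
                             read_length = 150, error_rate = 0.001,
                             total_bases = 30 * n_genomes * genome_length,
                             mobile_cog_fraction_in_islands = 0.8,
                             contig_margin = 200, gene_length = 900,
                             trna_per_genome = 4, rrna_per_genome = 1,
                             seed = 1) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length),
    abundance_mu = abundance_mu, abundance_sigma = abundance_sigma,
    islands_per_genome = as.integer(islands_per_genome),
    n_island_genomes = as.integer(min(n_island_genomes, n_genomes)),
    island_length = as.integer(island_length),
    island_snp_density = island_snp_density,
    background_snp_density = background_snp_density,
    minor_haplotype_freq = minor_haplotype_freq,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    total_bases = total_bases,
    mobile_cog_fraction_in_islands = mobile_cog_fraction_in_islands,
    contig_margin = as.integer(contig_margin),
    gene_length = as.integer(gene_length),
    trna_per_genome = as.integer(trna_per_genome),
    rrna_per_genome = as.integer(rrna_per_genome),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genomes >= 1, cfg$genome_length >= 1000,
    cfg$islands_per_genome >= 0, cfg$island_length >= 0,
    cfg$island_snp_density >= 0, cfg$background_snp_density >= 0,
    cfg$minor_haplotype_freq > 0, cfg$minor_haplotype_freq <= 0.5,
    cfg$read_length >= 20, cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$total_bases > 0, cfg$contig_margin >= 0,
    cfg$mobile_cog_fraction_in_islands >= 0,
    cfg$mobile_cog_fraction_in_islands <= 1
  )
  region_len <- cfg$genome_length - 2L * cfg$contig_margin
  if (cfg$islands_per_genome * cfg$island_length > region_len) {
    stop("islands do not fit: islands_per_genome * island_length exceeds ",
         "the contig region")
  }
  structure(cfg, class = "community_config")
}

# non-mobilome COG letters used for uniform background assignment
.cog_background <- c("C", "E", "G", "J", "K", "L", "M", "P", "T", "V")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq_chars, pos) {
  # replace bases at pos with a uniformly chosen different base
  bases <- c("A", "C", "G", "T")
  old <- seq_chars[pos]
  pick <- vapply(old, function(b) sample(setdiff(bases, b), 1), "")
  seq_chars[pos] <- pick
  seq_chars
}

#' Generate a synthetic community with planted structure
#'
#' Draws the genomes, haplotypes, islands, gene annotations, bins and
#' per-window ground truth implied by a [community_config()]. The same seed
#' always yields byte-identical outputs. Islands are placed one per equal
#' block of the contig region, uniformly within the block, so they never
#' overlap.
#'
#' @param config A [community_config()].
#' @return A `community` list with elements `config`, `contigs` (reference
#'   contig tibble), `haplotypes` (per genome: major/minor full-genome
#'   sequences), `islands` (contig coordinates), `genes` (annotation
#'   tibble, contig coordinates), `bins`, `truth` (per-window ground truth:
#'   `window_id`, `true_mean_depth`, `planted_snp_count`, `island_member`),
#'   and `abundances`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  cfg <- config
  with_seed(cfg$seed, {
    abund <- rlnorm(cfg$n_genomes, cfg$abundance_mu, cfg$abundance_sigma)
    abund <- abund / sum(abund)
    margin <- cfg$contig_margin
    L <- cfg$genome_length
    region_len <- L - 2L * margin

    genomes <- vapply(seq_len(cfg$n_genomes), function(i) random_dna(L), "")
    gids <- sprintf("g%d", seq_len(cfg$n_genomes))

    # islands: one per equal block of the contig region (contig coords)
    islands <- purrr::map(seq_len(cfg$n_genomes), function(i) {
      ni <- if (i <= cfg$n_island_genomes) cfg$islands_per_genome else 0L
      if (ni == 0) {
        return(tibble(contig_id = character(), start = integer(),
                      end = integer()))
      }
      block <- region_len %/% ni
      start <- vapply(seq_len(ni), function(b) {
        lo <- (b - 1L) * block + 1L
        hi <- b * block - cfg$island_length + 1L
        as.integer(lo + floor(runif(1) * max(1, hi - lo + 1)))
      }, 0L)
      tibble(contig_id = gids[i], start = start,
             end = start + cfg$island_length - 1L)
    }) %>% dplyr::bind_rows()

    # minor haplotype substitutions (genome coords)
    hap <- purrr::map(seq_len(cfg$n_genomes), function(i) {
      chars <- strsplit(genomes[i], "")[[1]]
      dens <- rep(cfg$background_snp_density, L)
      isl <- islands[islands$contig_id == gids[i], ]
      for (j in seq_len(nrow(isl))) {
        dens[(isl$start[j] + margin):(isl$end[j] + margin)] <-
          cfg$island_snp_density
      }
      pos <- which(runif(L) < dens)
      minor_chars <- if (length(pos) > 0) {
        substitute_bases(chars, pos)
      } else chars
      list(
        snp_pos = pos,
        ref = chars[pos],
        alt = minor_chars[pos],
        minor = paste(minor_chars, collapse = "")
      )
    })

    contigs <- tibble(
      contig_id = gids,
      sequence = substring(genomes, margin + 1L, L - margin),
      length = region_len
    )

    # planted variants in contig coordinates
    variants <- purrr::map(seq_len(cfg$n_genomes), function(i) {
      p <- hap[[i]]$snp_pos
      keep <- p > margin & p <= L - margin
      tibble(chrom = gids[i], pos = p[keep] - margin,
             ref = hap[[i]]$ref[keep], alt = hap[[i]]$alt[keep],
             qual = NA_real_, af = cfg$minor_haplotype_freq)
    }) %>% dplyr::bind_rows()

    # gene annotations (contig coordinates)
    genes <- purrr::map(seq_len(cfg$n_genomes), function(i) {
      starts <- seq(1L, region_len - cfg$gene_length + 1L,
                    by = cfg$gene_length)
      g <- tibble(
        contig_id = gids[i],
        start = as.integer(starts),
        end = as.integer(starts + cfg$gene_length - 1L),
        strand = rep_len(c("+", "-"), length(starts)),
        gene_type = "CDS"
      )
      extra_len <- c(rep(76L, cfg$trna_per_genome),
                     rep(1500L, cfg$rrna_per_genome))
      extra_type <- c(rep("tRNA", cfg$trna_per_genome),
                      rep("rRNA", cfg$rrna_per_genome))
      if (length(extra_len) > 0) {
        es <- vapply(extra_len, function(el) {
          as.integer(1L + floor(runif(1) * (region_len - el)))
        }, 0L)
        g <- dplyr::bind_rows(g, tibble(
          contig_id = gids[i], start = es, end = es + extra_len - 1L,
          strand = rep_len(c("+", "-"), length(es)), gene_type = extra_type))
      }
      isl <- islands[islands$contig_id == gids[i], ]
      mid <- (g$start + g$end) %/% 2L
      in_island <- rep(FALSE, nrow(g))
      for (j in seq_len(nrow(isl))) {
        in_island <- in_island | (mid >= isl$start[j] & mid <= isl$end[j])
      }
      cog <- ifelse(
        g$gene_type != "CDS", "",
        ifelse(in_island & runif(nrow(g)) <
                 cfg$mobile_cog_fraction_in_islands,
               "X", sample(.cog_background, nrow(g), replace = TRUE)))
      g$cog_categories <- cog
      g$island_member <- in_island
      g
    }) %>% dplyr::bind_rows()
    genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "contig_id", "start", "end", "strand",
                       "gene_type", "cog_categories", "island_member")]

    bins <- tibble(contig_id = gids,
                   bin_id = sprintf("bin%d", seq_len(cfg$n_genomes)))

    # per-window ground truth
    n_reads <- round(cfg$total_bases / cfg$read_length)
    exp_depth <- abund * n_reads * cfg$read_length / L
    windows <- make_windows(contigs, width = 1000, step = 500)
    truth <- windows[, c("window_id", "contig_id", "start0", "end0")]
    truth$true_mean_depth <- exp_depth[match(truth$contig_id, gids)]
    snp_contig <- split(variants$pos, variants$chrom)
    truth$planted_snp_count <- purrr::pmap_int(
      list(truth$contig_id, truth$start0, truth$end0),
      function(cid, s0, e0) {
        p <- snp_contig[[cid]]
        if (is.null(p)) 0L else sum(p > s0 & p <= e0)
      })
    isl_contig <- split(islands, islands$contig_id)
    truth$island_member <- purrr::pmap_lgl(
      list(truth$contig_id, truth$start0, truth$end0),
      function(cid, s0, e0) {
        isl <- isl_contig[[cid]]
        if (is.null(isl)) return(FALSE)
        ov <- pmin(isl$end, e0) - pmax(isl$start, s0 + 1L) + 1L
        sum(pmax(ov, 0L)) >= (e0 - s0) / 2
      })

    structure(list(
      config = cfg,
      contigs = contigs,
      haplotypes = tibble(
        contig_id = gids,
        major = genomes,
        minor = vapply(hap, function(h) h$minor, "")
      ),
      islands = islands,
      variants = variants,
      genes = genes,
      bins = bins,
      truth = truth,
      abundances = tibble(contig_id = gids, abundance = abund)
    ), class = "community")
  })
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf(
    "community: %d genome(s) of %d bp, %d planted SNP(s), %d gene(s)\n",
    x$config$n_genomes, x$config$genome_length, nrow(x$variants),
    nrow(x$genes)))
  invisible(x)
}

#' Simulate single-end short reads from a community
#'
#' Draws reads from the genomes in proportion to their lognormal
#' abundances; each read comes from the minor haplotype with probability
#' `minor_haplotype_freq`, starts uniformly along the genome, has uniform
#' strand, and receives i.i.d. substitution errors at `error_rate`.
#'
#' @param community A community from [simulate_community()].
#' @param seed Optional seed; defaults to `config$seed + 1` so reads are
#'   reproducible yet independent of the community draw.
#' @return A tibble with `read_id`, `sequence`, and provenance columns
#'   `contig_id` (source genome), `hap`, `start`, `end` (genome
#'   coordinates), `strand`.
#' @export
simulate_reads <- function(community, seed = NULL) {
  stopifnot(inherits(community, "community"))
  cfg <- community$config
  if (cfg$read_length > cfg$genome_length) {
    stop("read_length exceeds genome_length")
  }
  if (is.null(seed)) seed <- cfg$seed + 1L
  with_seed(seed, {
    n_reads <- round(cfg$total_bases / cfg$read_length)
    rl <- cfg$read_length
    L <- cfg$genome_length
    abund <- community$abundances$abundance
    gidx <- sample.int(cfg$n_genomes, n_reads, replace = TRUE, prob = abund)
    minor <- runif(n_reads) < cfg$minor_haplotype_freq
    start <- 1L + as.integer(floor(runif(n_reads) * (L - rl + 1L)))
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs <- character(n_reads)
    for (i in seq_len(cfg$n_genomes)) {
      for (m in c(FALSE, TRUE)) {
        sel <- gidx == i & minor == m
        if (!any(sel)) next
        src <- if (m) community$haplotypes$minor[i]
               else community$haplotypes$major[i]
        seqs[sel] <- substring(src, start[sel], start[sel] + rl - 1L)
      }
    }
    # substitution errors
    n_err <- rbinom(n_reads, rl, cfg$error_rate)
    for (i in which(n_err > 0)) {
      chars <- strsplit(seqs[i], "")[[1]]
      pos <- sample.int(rl, n_err[i])
      chars <- substitute_bases(chars, pos)
      seqs[i] <- paste(chars, collapse = "")
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
    tibble(
      read_id = sprintf("r%07d", seq_len(n_reads)),
      sequence = seqs,
      contig_id = community$contigs$contig_id[gidx],
      hap = ifelse(minor, "minor", "major"),
      start = start,
      end = start + rl - 1L,
      strand = strand
    )
  })
}

#' Reference placements of simulated reads
#'
#' Converts the genome-coordinate provenance of simulated reads into
#' reference-contig placements (the contigs are the genomes trimmed by
#' `contig_margin`), clipping to the contig and dropping reads wholly
#' outside it. No read mapping is involved: placements come from the known
#' source interval of each read, but the emitted table has the same shape a
#' mapping would produce.
#'
#' @param reads Output of [simulate_reads()].
#' @param community The community the reads were simulated from.
#' @return A placements tibble (`read_id`, `contig_id`, `start`, `end`).
#' @export
simulated_placements <- function(reads, community) {
  cfg <- community$config
  margin <- cfg$contig_margin
  clen <- cfg$genome_length - 2L * margin
  tibble(
    read_id = reads$read_id,
    contig_id = reads$contig_id,
    start = pmax(1L, reads$start - margin),
    end = pmin(clen, reads$end - margin)
  ) %>%
    dplyr::filter(.data$start <= clen, .data$end >= 1L)
}

#' Emit the per-base depth table and the VCF of planted variants
#'
#' Depth at each reference position is the number of reads whose true
#' source interval covers it; the VCF lists the planted minor-haplotype
#' substitutions with their allele frequency. Both come from read
#' provenance, so no mapping or variant calling is run, but the files have
#' the exact formats those tools would produce.
#'
#' @param reads Output of [simulate_reads()].
#' @param community The community the reads were simulated from.
#' @return A list with `depth` (tibble `name`, `pos`, `depth`; covered
#'   positions only) and `variants` (tibble `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `af`).
#' @export
emit_depth_and_variants <- function(reads, community) {
  pl <- simulated_placements(reads, community)
  clen <- community$config$genome_length - 2L * community$config$contig_margin
  depth <- purrr::map(community$contigs$contig_id, function(cid) {
    sel <- pl$contig_id == cid
    if (!any(sel)) {
      return(tibble(name = character(), pos = integer(), depth = integer()))
    }
    cov <- IRanges::coverage(
      IRanges::IRanges(start = pl$start[sel], end = pl$end[sel]),
      width = clen)
    v <- as.integer(cov)
    nz <- which(v > 0)
    tibble(name = cid, pos = nz, depth = v[nz])
  }) %>% dplyr::bind_rows()
  list(depth = depth, variants = community$variants)
}

#' Toy unitig assembler
#'
#' Stands in for a short-read assembler so the pipeline can be exercised
#' end-to-end: builds the canonical compacted de Bruijn graph of the reads
#' and emits every maximal non-branching path as a contig. K-mers seen
#' fewer than `min_count` times are dropped, and, as in real assemblers
#' whose coverage cutoff scales with sequencing depth, so are k-mers below
#' `cov_frac` times the median multiplicity of the non-singleton k-mer
#' spectrum; without the relative cutoff, recurrent sequencing errors at
#' high depth would masquerade as low-frequency strain variation. Circular unitigs are linearized
#' with the first k-1 bases appended so any substring of the original cycle
#' appears contiguously. Contigs are reported in a strand-canonical form
#' (the lexicographic minimum of the sequence and its reverse complement)
#' and sorted, so output order is deterministic. Running it at two
#' different k values yields two different "assemblers" for consistency
#' analysis.
#'
#' @param reads Character vector, tibble with a `sequence` column, or
#'   DNAStringSet.
#' @param k K-mer size (odd, 11..63).
#' @param min_count Minimum k-mer multiplicity (default 2, so singleton
#'   error k-mers do not shatter contigs).
#' @param cov_frac Relative coverage cutoff as a fraction of the median
#'   multiplicity of k-mers passing `min_count` (default 0.1; set 0 to
#'   disable).
#' @param label Prefix for contig ids (default `"ctg"`).
#' @return A contig tibble (`contig_id`, `sequence`, `length`).
#' @export
toy_assemble <- function(reads, k, min_count = 2, cov_frac = 0.1,
                         label = "ctg") {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- as.character(reads)
  cutoff <- min_count
  if (cov_frac > 0 && length(reads) > 0) {
    counts <- cpp_kmer_counts(reads, as.integer(k))
    counts <- counts[counts >= min_count]
    if (length(counts) > 0) {
      cutoff <- max(min_count, ceiling(cov_frac * median(counts)))
    }
  }
  g <- build_unitig_graph(reads, k = k, min_count = cutoff)
  nodes <- g$nodes
  if (nrow(nodes) == 0) {
    return(tibble(contig_id = character(), sequence = character(),
                  length = integer()))
  }
  seqs <- nodes$sequence
  circ <- nodes$circular
  if (any(circ)) {
    seqs[circ] <- paste0(seqs[circ], substring(seqs[circ], 1, k - 1))
  }
  rc <- reverse_complement(seqs)
  seqs <- pmin(seqs, rc)
  seqs <- sort(seqs)
  tibble(
    contig_id = sprintf("%s%05d", label, seq_along(seqs)),
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write all simulator outputs to a directory
#'
#' Writes the standard-format files consumed by [run_pipeline()]:
#' `reference.fasta`, `reads.fastq`, `depth.tsv`, `variants.vcf`,
#' `annotations.tsv`, `bins.tsv`, `placements.tsv`, `truth_windows.tsv`.
#'
#' @param community A community from [simulate_community()].
#' @param reads Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_community <- function(community, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    reference = file.path(dir, "reference.fasta"),
    reads = file.path(dir, "reads.fastq"),
    depth = file.path(dir, "depth.tsv"),
    variants = file.path(dir, "variants.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    bins = file.path(dir, "bins.tsv"),
    placements = file.path(dir, "placements.tsv"),
    truth = file.path(dir, "truth_windows.tsv")
  )
  write_contigs_fasta(community$contigs, p$reference)
  write_reads_fastq(reads, p$reads)
  dv <- emit_depth_and_variants(reads, community)
  write_depth_table(dv$depth, p$depth)
  write_vcf(dv$variants, p$variants,
            contig_lengths = setNames(community$contigs$length,
                                      community$contigs$contig_id))
  write_gene_annotations(community$genes, p$annotations)
  write_bin_assignments(community$bins, p$bins)
  write_placements(simulated_placements(reads, community), p$placements)
  write_hashed_tsv(community$truth, p$truth)
  invisible(p)
}
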