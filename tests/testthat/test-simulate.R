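test_that("the community draw is fully determined by the seed", {
  cfg <- community_config(n_genomes = 2, genome_length = 10000,
                          islands_per_genome = 1, island_length = 2000,
                          total_bases = 5 * 2 * 10000, seed = 9)
  c1 <- simulate_community(cfg)
  c2 <- simulate_community(cfg)
  expect_identical(c1$contigs, c2$contigs)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$genes, c2$genes)
  r1 <- simulate_reads(c1)
  r2 <- simulate_reads(c2)
  expect_identical(r1, r2)
  # and a different seed gives different genomes
  c3 <- simulate_community(community_config(
    n_genomes = 2, genome_length = 10000, islands_per_genome = 1,
    island_length = 2000, total_bases = 5 * 2 * 10000, seed = 10))
  expect_false(identical(c1$contigs$sequence, c3$contigs$sequence))
})

test_that("no diversity configured means identical haplotypes", {
  cfg <- community_config(n_genomes = 1, genome_length = 8000,
                          islands_per_genome = 0,
                          background_snp_density = 0,
                          total_bases = 10 * 8000, seed = 11)
  com <- simulate_community(cfg)
  expect_identical(com$haplotypes$major, com$haplotypes$minor)
  expect_equal(nrow(com$variants), 0)
  expect_true(all(com$truth$planted_snp_count == 0))
  expect_false(any(com$truth$island_member))
})

test_that("planted island SNP counts fall within binomial bounds", {
  cfg <- community_config(n_genomes = 1, genome_length = 50000,
                          islands_per_genome = 2, island_length = 5000,
                          island_snp_density = 0.01,
                          background_snp_density = 0,
                          total_bases = 50000, seed = 12)
  com <- simulate_community(cfg)
  n <- nrow(com$variants)
  bounds <- stats::qbinom(c(0.0005, 0.9995), 10000, 0.01)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
  # all variants lie inside islands
  in_island <- purrr::map2_lgl(com$variants$chrom, com$variants$pos,
    function(cid, p) {
      isl <- com$islands[com$islands$contig_id == cid, ]
      any(p >= isl$start & p <= isl$end)
    })
  expect_true(all(in_island))
  # VCF records match the haplotype diff
  expect_true(all(com$variants$ref != com$variants$alt))
})

test_that("error-free major-only reads are exact reference substrings", {
  cfg <- community_config(n_genomes = 1, genome_length = 8000,
                          islands_per_genome = 0,
                          background_snp_density = 0, error_rate = 0,
                          minor_haplotype_freq = 1e-9,
                          total_bases = 5 * 8000, seed = 13)
  com <- simulate_community(cfg)
  reads <- simulate_reads(com)
  genome <- com$haplotypes$major[1]
  for (i in sample.int(nrow(reads), 25)) {
    s <- reads$sequence[i]
    if (reads$strand[i] == "-") s <- revcomp_chr(s)
    expect_identical(s, substr(genome, reads$start[i], reads$end[i]))
  }
})

test_that("read counts track configured abundances", {
  cfg <- community_config(n_genomes = 2, genome_length = 10000,
                          islands_per_genome = 0, error_rate = 0,
                          total_bases = 30 * 2 * 10000, seed = 14)
  com <- simulate_community(cfg)
  com$abundances$abundance <- c(0.9, 0.1)
  reads <- simulate_reads(com)
  n1 <- sum(reads$contig_id == "g1")
  bounds <- stats::qbinom(c(0.0005, 0.9995), nrow(reads), 0.9)
  expect_gte(n1, bounds[1])
  expect_lte(n1, bounds[2])
})

test_that("depth and variant emission are exact bookkeeping", {
  cfg <- community_config(n_genomes = 1, genome_length = 5000,
                          islands_per_genome = 1, island_length = 1000,
                          island_snp_density = 0.01, contig_margin = 200,
                          error_rate = 0, total_bases = 2 * 5000, seed = 15)
  com <- simulate_community(cfg)
  reads <- simulate_reads(com)
  dv <- emit_depth_and_variants(reads, com)
  # single-read check: a read fully inside the contig covers exactly its
  # interval (in contig coordinates)
  one <- reads[reads$start > 300 & reads$end < 4500, ][1, ]
  dv1 <- emit_depth_and_variants(one, com)
  expect_equal(dv1$depth$pos, (one$start - 200):(one$end - 200))
  expect_true(all(dv1$depth$depth == 1L))
  # zero reads: empty depth
  dv0 <- emit_depth_and_variants(reads[0, ], com)
  expect_equal(nrow(dv0$depth), 0)
  # depth sums to the clipped read bases
  pl <- simulated_placements(reads, com)
  expect_equal(sum(dv$depth$depth), sum(pl$end - pl$start + 1))
  # planted variants carry the configured allele frequency
  expect_true(all(dv$variants$af == cfg$minor_haplotype_freq))
})

test_that("the toy assembler reconstructs a clean haplotype and breaks at
           bubbles", {
  com <- clean_community(seed = 16, depth = 30, genome_length = 12000,
                         n_genomes = 1)
  reads <- simulate_reads(com)
  asm <- toy_assemble(reads, k = 21)
  expect_equal(nrow(asm), 1)
  # the contig covers the reference contig (trimmed genome) entirely
  expect_true(grepl(com$contigs$sequence[1], asm$sequence[1], fixed = TRUE) ||
              grepl(revcomp_chr(com$contigs$sequence[1]), asm$sequence[1],
                    fixed = TRUE))
  # a strain mixture with interior SNPs cannot be spanned by one contig
  cfg2 <- community_config(n_genomes = 1, genome_length = 12000,
                           islands_per_genome = 1, island_length = 3000,
                           island_snp_density = 0.005,
                           minor_haplotype_freq = 0.3, error_rate = 0,
                           total_bases = 200 * 12000, seed = 17)
  com2 <- simulate_community(cfg2)
  reads2 <- simulate_reads(com2)
  asm2 <- toy_assemble(reads2, k = 21)
  expect_gt(nrow(asm2), 2)
  expect_lt(max(asm2$length), 12000 - 100)
  # determinism of assembly output
  expect_identical(asm2, toy_assemble(reads2, k = 21))
})

test_that("island geometry is validated", {
  expect_error(
    community_config(n_genomes = 1, genome_length = 10000,
                     islands_per_genome = 3, island_length = 4000),
    "islands do not fit")
})
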