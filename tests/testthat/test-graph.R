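test_that("single reads and tiling reads compact to single unitigs", {
  set.seed(31)
  r <- rdna(40)
  expect_equal(nrow(asmgaps:::cpp_kmer_table(r, 31)), 10)  # 40 - 31 + 1
  g <- build_unitig_graph(r, k = 31)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(g$nodes$length, 40L)
  expect_equal(nrow(g$edges), 0)
  # error-free reads tiling a 1000 bp haplotype end-to-end
  hap <- rdna(1000)
  starts <- seq(1, 1000 - 150 + 1, by = 10)
  reads <- substring(hap, starts, starts + 149)
  g2 <- build_unitig_graph(reads, k = 31)
  expect_equal(nrow(g2$nodes), 1)
  expect_true(g2$nodes$sequence %in% c(hap, revcomp_chr(hap)))
})

test_that("one interior SNP produces the canonical 4-node bubble", {
  set.seed(32)
  k <- 31
  h1 <- rdna(300)
  h2 <- h1
  old <- substr(h1, 150, 150)
  substr(h2, 150, 150) <- setdiff(c("A", "C", "G", "T"), old)[1]
  g <- build_unitig_graph(c(h1, h2), k = k)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
  # the two variant unitigs span 2k-1 bases
  expect_equal(sort(g$nodes$length)[1:2], rep(2L * k - 1L, 2))
  # reference marking: window = h1 flags both flanks plus the major branch
  g <- mark_reference_nodes(g, h1)
  expect_equal(length(g$reference_nodes), 3)
  m <- compute_graph_metrics(g)
  expect_equal(m$graph_size, 4L)
  expect_equal(m$n_reference_nodes, 3L)
  expect_equal(m$surrounding_nodes, 1L)
  # an unrelated window flags nothing
  g0 <- mark_reference_nodes(g, rdna(300))
  expect_length(g0$reference_nodes, 0)
  expect_error(mark_reference_nodes(g, rdna(10)), "shorter than k")
})

test_that("canonical k-mers are conserved by compaction (multiset equality)", {
  set.seed(33)
  for (i in 1:5) {
    reads <- replicate(30, rdna(sample(20:60, 1)))
    g <- build_unitig_graph(reads, k = 15)
    got <- naive_kmer_table(g$nodes$sequence, 15)$kmer
    expected <- naive_kmer_table(reads, 15)$kmer
    expect_identical(sort(got), sort(expected), info = i)
  }
  # min_count drops singletons
  reads <- c(rdna(50), rdna(50))
  g1 <- build_unitig_graph(c(reads, reads[1]), k = 15, min_count = 2)
  expect_identical(sort(naive_kmer_table(g1$nodes$sequence, 15)$kmer),
                   sort(naive_kmer_table(reads[1], 15)$kmer))
})

test_that("the graph is fully compacted (no mergeable adjacent nodes)", {
  set.seed(34)
  # strain mixture generates a branched graph
  h1 <- rdna(500)
  h2 <- mutate_seq(h1, n_sub = 6)
  starts <- seq(1, 351, by = 7)
  reads <- c(substring(h1, starts, starts + 149),
             substring(h2, starts, starts + 149))
  g <- build_unitig_graph(reads, k = 21)
  expect_gt(nrow(g$nodes), 4)
  # node degree per (node, side): a node end with exactly one neighbour
  # whose own end also has exactly one neighbour would be mergeable
  ends <- rbind(
    data.frame(node = g$edges$from, side = g$edges$from_orient,
               other = g$edges$to, other_side = g$edges$to_orient),
    data.frame(node = g$edges$to,
               side = ifelse(g$edges$to_orient == "+", "-", "+"),
               other = g$edges$from,
               other_side = ifelse(g$edges$from_orient == "+", "-", "+")))
  deg <- stats::aggregate(other ~ node + side, ends, length)
  get_deg <- function(nd, sd) {
    v <- deg$other[deg$node == nd & deg$side == sd]
    if (length(v) == 0) 0 else v
  }
  for (i in seq_len(nrow(ends))) {
    if (get_deg(ends$node[i], ends$side[i]) == 1) {
      # the unique partner must not reciprocate uniquely (else not compact),
      # unless it is a self-loop / palindromic arrangement
      partner_side <- ifelse(ends$other_side[i] == "+", "+", "-")
      back <- get_deg(ends$other[i], ifelse(partner_side == "+", "-", "+"))
      expect_true(back != 1 || ends$other[i] == ends$node[i])
    }
  }
})

test_that("surrounding nodes follow BFS distance on a linear chain", {
  # chain R - D - E - F - G with R the only reference node
  g <- structure(list(
    k = 31L,
    nodes = tibble::tibble(
      node_id = c("R", "D", "E", "F", "G"),
      sequence = NA_character_, length = 40L, mean_count = 1,
      circular = FALSE),
    edges = tibble::tibble(
      from = c("R", "D", "E", "F"), from_orient = "+",
      to = c("D", "E", "F", "G"), to_orient = "+"),
    reference_nodes = "R"), class = "unitig_graph")
  m <- compute_graph_metrics(g, max_dist = 3)
  expect_equal(m$surrounding_nodes, 3L)  # D, E, F; G is at distance 4
  # isolated reference node
  g1 <- structure(list(
    k = 31L,
    nodes = tibble::tibble(node_id = "R", sequence = NA_character_,
                           length = 40L, mean_count = 1, circular = FALSE),
    edges = tibble::tibble(from = character(), from_orient = character(),
                           to = character(), to_orient = character()),
    reference_nodes = "R"), class = "unitig_graph")
  expect_equal(compute_graph_metrics(g1)$surrounding_nodes, 0L)
  # all nodes reference: only non-reference nodes are counted
  g2 <- g
  g2$reference_nodes <- g$nodes$node_id
  expect_equal(compute_graph_metrics(g2)$surrounding_nodes, 0L)
})

test_that("GFA export round-trips to an isomorphic graph", {
  set.seed(35)
  h1 <- rdna(300)
  h2 <- h1
  substr(h2, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                  substr(h1, 150, 150))[1]
  g <- mark_reference_nodes(build_unitig_graph(c(h1, h2), k = 31), h1)
  path <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "S")), 4)
  expect_equal(sum(startsWith(lines, "L")), 4)
  back <- read_gfa(path)
  expect_equal(back$k, g$k)
  expect_setequal(back$nodes$sequence, g$nodes$sequence)
  expect_equal(nrow(back$edges), nrow(g$edges))
  expect_setequal(back$reference_nodes, g$reference_nodes)
  expect_equal(compute_graph_metrics(back)[, -1],
               compute_graph_metrics(g)[, -1])
  # degenerate graphs
  g1 <- build_unitig_graph(rdna(50), k = 31)
  write_gfa(g1, path)
  expect_equal(sum(startsWith(readLines(path), "S")), 1)
  g0 <- build_unitig_graph(character(), k = 31)
  write_gfa(g0, path)
  expect_equal(readLines(path), sprintf("H\tVN:Z:1.0\tKM:i:%d", 31))
})

test_that("graph size grows with planted SNP density", {
  set.seed(36)
  dens_grid <- rep(c(0, 0.002, 0.005, 0.01, 0.02, 0.04), each = 3)
  sizes <- sapply(dens_grid, function(dens) {
    h1 <- rdna(1000)
    n_snp <- round(dens * 1000)
    h2 <- if (n_snp > 0) mutate_seq(h1, n_sub = n_snp) else h1
    starts <- seq(1, 851, by = 3)
    reads <- c(substring(h1, starts, starts + 149),
               substring(h2, starts, starts + 149))
    nrow(build_unitig_graph(reads, k = 31)$nodes)
  })
  ct <- suppressWarnings(
    stats::cor.test(dens_grid, sizes, method = "spearman",
                    alternative = "greater"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
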