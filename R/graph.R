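#' Build a compacted de Bruijn graph from reads
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) across the reads, discards k-mers seen fewer than `min_count`
#' times, and compacts the bidirected de Bruijn graph into unitigs (maximal
#' non-branching paths). Node mean coverage is the average multiplicity of
#' the node's constituent k-mers; edges record the (k-1)-overlaps between
#' unitig ends with their orientations. Reads shorter than k are skipped,
#' and k-mers containing ambiguous bases are ignored.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column, or a [Biostrings::DNAStringSet].
#' @param k K-mer size; odd, between 11 and 63 (default 31).
#' @param min_count Minimum k-mer multiplicity to keep (default 1: no
#'   abundance filtering).
#' @return A `unitig_graph` object: a list with `k`, `nodes` (tibble
#'   `node_id`, `sequence`, `length`, `mean_count`, `circular`), `edges`
#'   (tibble `from`, `from_orient`, `to`, `to_orient`) and
#'   `reference_nodes` (character, empty until [mark_reference_nodes()]).
#' @export
build_unitig_graph <- function(reads, k = 31, min_count = 1) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- as.character(reads)
  if (k %% 2 == 0 || k < 11 || k > 63) {
    stop("k must be odd and between 11 and 63")
  }
  raw <- cpp_build_unitigs(reads, as.integer(k), as.integer(min_count))
  n <- length(raw$sequence)
  ids <- if (n > 0) sprintf("u%d", seq_len(n)) else character()
  nodes <- tibble(
    node_id = ids,
    sequence = as.character(raw$sequence),
    length = as.integer(raw$length),
    mean_count = as.numeric(raw$mean_count),
    circular = as.logical(raw$circular)
  )
  edges <- tibble(
    from = ids[raw$edge_from],
    from_orient = as.character(raw$edge_from_orient),
    to = ids[raw$edge_to],
    to_orient = as.character(raw$edge_to_orient)
  )
  structure(list(k = as.integer(k), nodes = nodes, edges = edges,
                 reference_nodes = character()),
            class = "unitig_graph")
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat(sprintf(
    "unitig_graph: k=%d, %d nodes, %d edges, %d reference node(s)\n",
    x$k, nrow(x$nodes), nrow(x$edges), length(x$reference_nodes)))
  invisible(x)
}

#' Flag the unitigs carrying the reference path
#'
#' A node is flagged as a reference node when it shares at least one
#' canonical k-mer with the window sequence. At k = 31 a shared k-mer
#' implies high local identity over the k-mer span, so the flagged nodes
#' trace the reference path through the graph.
#'
#' @param graph A `unitig_graph` from [build_unitig_graph()].
#' @param window The window sequence (a string), or a one-row window tibble
#'   with a `sequence` column.
#' @return The graph with `reference_nodes` set.
#' @export
mark_reference_nodes <- function(graph, window) {
  stopifnot(inherits(graph, "unitig_graph"))
  if (is.data.frame(window)) window <- window$sequence
  window <- as.character(window)
  stopifnot(length(window) == 1)
  if (nchar(window) < graph$k) {
    stop("window shorter than k = ", graph$k)
  }
  if (nrow(graph$nodes) == 0) {
    graph$reference_nodes <- character()
    return(graph)
  }
  hit <- cpp_shares_kmer(graph$nodes$sequence, window, graph$k)
  graph$reference_nodes <- graph$nodes$node_id[hit]
  graph
}

#' Graph size and surrounding-node metrics
#'
#' Summarizes a reference-marked unitig graph: `graph_size` is the total
#' node count; `surrounding_nodes` counts the non-reference nodes within
#' graph distance `max_dist` (number of edges on the undirected node graph,
#' orientation ignored) of any reference node, found by multi-source
#' breadth-first search. Coverage summaries of the reference and
#' off-reference nodes are included.
#'
#' @param graph A `unitig_graph`, normally after [mark_reference_nodes()].
#' @param max_dist Maximum graph distance for a node to count as
#'   surrounding (default 3).
#' @param window_id Optional id recorded in the output.
#' @return A one-row tibble: `window_id`, `graph_size`,
#'   `n_reference_nodes`, `surrounding_nodes`, `mean_ref_node_coverage`,
#'   `max_offref_coverage`.
#' @export
compute_graph_metrics <- function(graph, max_dist = 3, window_id = NA_character_) {
  stopifnot(inherits(graph, "unitig_graph"))
  nodes <- graph$nodes
  ref <- graph$reference_nodes
  n_ref <- length(ref)
  surrounding <- 0L
  if (n_ref > 0 && nrow(nodes) > n_ref) {
    g <- igraph::graph_from_data_frame(
      unique(graph$edges[, c("from", "to")]),
      directed = FALSE, vertices = nodes$node_id)
    d <- igraph::distances(g, v = ref, to = igraph::V(g))
    dmin <- apply(d, 2, min)
    surrounding <- sum(dmin >= 1 & dmin <= max_dist)
  }
  is_ref <- nodes$node_id %in% ref
  tibble(
    window_id = window_id,
    graph_size = nrow(nodes),
    n_reference_nodes = n_ref,
    surrounding_nodes = as.integer(surrounding),
    mean_ref_node_coverage = if (n_ref > 0) mean(nodes$mean_count[is_ref])
                             else NA_real_,
    max_offref_coverage = if (any(!is_ref)) max(nodes$mean_count[!is_ref])
                          else NA_real_
  )
}

#' Per-window de Bruijn graph metrics
#'
#' For each window, builds the compacted de Bruijn graph of the reads whose
#' placement overlaps the window by at least one base, marks the reference
#' nodes with the window sequence, and computes [compute_graph_metrics()].
#'
#' @param reads A tibble with `read_id` and `sequence`.
#' @param placements A tibble with `read_id`, `contig_id`, `start`, `end`
#'   (1-based inclusive reference intervals; see [read_placements()]).
#' @param windows A window tibble with sequences.
#' @param k Passed to [build_unitig_graph()].
#' @param min_count Minimum k-mer multiplicity for the per-window graphs
#'   (default 2, the abundance cutoff of standard compacted-graph
#'   constructors; singleton sequencing-error k-mers otherwise dominate
#'   graph size at high depth and mask the diversity signal).
#' @param max_dist Passed to [compute_graph_metrics()].
#' @return A tibble with one row per window (see [compute_graph_metrics()]),
#'   plus `n_reads` used per window.
#' @export
window_graph_metrics <- function(reads, placements, windows, k = 31,
                                 min_count = 2, max_dist = 3) {
  pl <- dplyr::inner_join(placements[, c("read_id", "contig_id",
                                         "start", "end")],
                          reads[, c("read_id", "sequence")],
                          by = "read_id")
  if (nrow(pl) < nrow(placements)) {
    warning(sprintf("%d placement(s) without a matching read",
                    nrow(placements) - nrow(pl)))
  }
  res <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- pl$contig_id == w$contig_id &
      pl$end >= w$start0 + 1 & pl$start <= w$end0
    seqs <- pl$sequence[sel]
    g <- build_unitig_graph(seqs, k = k, min_count = min_count)
    g <- mark_reference_nodes(g, w$sequence)
    m <- compute_graph_metrics(g, max_dist = max_dist,
                               window_id = w$window_id)
    m$n_reads <- sum(sel)
    res[[i]] <- m
  }
  dplyr::bind_rows(res)
}

#' Export a unitig graph as GFA 1.0
#'
#' Writes S-lines with the unitig sequences (mean k-mer count as a `dp:f`
#' tag, reference flag as `RF:i`, circular flag as `CR:i`) and L-lines with
#' `(k-1)M` overlaps. The k-mer size is recorded in the header (`KM:i`), so
#' [read_gfa()] recovers an isomorphic graph.
#'
#' @param graph A `unitig_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "unitig_graph"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tKM:i:%d", graph$k), con)
  nodes <- graph$nodes
  if (nrow(nodes) > 0) {
    rf <- as.integer(nodes$node_id %in% graph$reference_nodes)
    writeLines(sprintf("S\t%s\t%s\tdp:f:%s\tRF:i:%d\tCR:i:%d",
                       nodes$node_id, nodes$sequence,
                       format(nodes$mean_count, trim = TRUE,
                              scientific = FALSE),
                       rf, as.integer(nodes$circular)), con)
  }
  e <- graph$edges
  if (nrow(e) > 0) {
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                       e$from, e$from_orient, e$to, e$to_orient,
                       graph$k - 1L), con)
  }
  invisible(path)
}

#' Import a unitig graph from GFA 1.0 written by [write_gfa()]
#'
#' @param path Path to the GFA file.
#' @return A `unitig_graph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  typ <- substring(lines, 1, 1)
  h <- strsplit(lines[typ == "H"][1], "\t", fixed = TRUE)[[1]]
  km <- h[startsWith(h, "KM:i:")]
  if (length(km) == 0) stop("GFA header lacks the KM:i k-mer tag")
  k <- as.integer(sub("KM:i:", "", km[1]))
  s <- strsplit(lines[typ == "S"], "\t", fixed = TRUE)
  get_tag <- function(fields, prefix, default = NA_character_) {
    v <- fields[startsWith(fields, prefix)]
    if (length(v) == 0) default else sub(prefix, "", v[1], fixed = TRUE)
  }
  nodes <- tibble(
    node_id = vapply(s, `[[`, "", 2),
    sequence = vapply(s, `[[`, "", 3),
    mean_count = as.numeric(vapply(s, get_tag, "", "dp:f:")),
    ref = vapply(s, get_tag, "", "RF:i:", default = "0") == "1",
    circular = vapply(s, get_tag, "", "CR:i:", default = "0") == "1"
  )
  nodes$length <- nchar(nodes$sequence)
  l <- strsplit(lines[typ == "L"], "\t", fixed = TRUE)
  edges <- tibble(
    from = vapply(l, `[[`, "", 2),
    from_orient = vapply(l, `[[`, "", 3),
    to = vapply(l, `[[`, "", 4),
    to_orient = vapply(l, `[[`, "", 5)
  )
  structure(list(
    k = k,
    nodes = nodes[, c("node_id", "sequence", "length", "mean_count",
                      "circular")],
    edges = edges,
    reference_nodes = nodes$node_id[nodes$ref]
  ), class = "unitig_graph")
}
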