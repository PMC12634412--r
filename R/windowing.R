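#' Read assembly contigs from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file into the tabular
#' contig representation used throughout the package. Record descriptions are
#' truncated at the first whitespace to form contig ids.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `sequence`, `length`.
#' @export
read_contigs <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dna))
  tibble(
    contig_id = ids,
    sequence = unname(as.character(dna)),
    length = Biostrings::width(dna)
  )
}

#' Write contigs to a FASTA file
#'
#' @param contigs A tibble with `contig_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  dna <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$contig_id))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Split contigs into fixed-width sliding windows
#'
#' Decomposes each contig into overlapping subsequences of exactly `width`
#' bp, advancing by `step` bp. These windows are the reference units for all
#' downstream scoring: keeping every window the same length makes per-window
#' metrics directly comparable. Trailing residue shorter than `width` is
#' discarded, so a contig of length `L` yields
#' `max(0, floor((L - width) / step) + 1)` windows. Contigs shorter than
#' `width` produce no windows; contigs with an empty sequence or characters
#' outside `A`, `C`, `G`, `T`, `N` are rejected with a warning.
#'
#' Window ids are `"{contig_id}:{start}-{end}"` in 1-based inclusive
#' coordinates; the `start0`/`end0` columns hold the 0-based half-open
#' internal coordinates.
#'
#' @param contigs A tibble with `contig_id` and `sequence` columns
#'   (e.g. from [read_contigs()]).
#' @param width Window width in bp (default 1000).
#' @param step Sliding step in bp (default 500); must satisfy
#'   `1 <= step <= width`.
#' @return A tibble with columns `window_id`, `contig_id`, `start0`, `end0`,
#'   `length`, `sequence`.
#' @examples
#' contigs <- tibble::tibble(contig_id = "c1",
#'                           sequence = strrep("ACGT", 500))
#' make_windows(contigs)
#' @export
make_windows <- function(contigs, width = 1000, step = 500) {
  stopifnot(width >= 1, step >= 1, step <= width)
  width <- as.integer(width)
  step <- as.integer(step)
  bad <- !grepl("^[ACGTNacgtn]+$", contigs$sequence)
  if (any(bad)) {
    warning(sprintf(
      "rejected %d contig(s) with empty or non-DNA sequence: %s",
      sum(bad), paste(head(contigs$contig_id[bad], 5), collapse = ", ")
    ))
    contigs <- contigs[!bad, , drop = FALSE]
  }
  lens <- nchar(contigs$sequence)
  n_short <- sum(lens < width)
  if (n_short > 0) {
    message(sprintf("%d contig(s) shorter than %d bp yield no windows",
                    n_short, width))
  }
  rows <- purrr::pmap(
    list(contigs$contig_id, contigs$sequence, lens),
    function(id, seq, len) {
      n <- if (len < width) 0L else (len - width) %/% step + 1L
      if (n == 0L) return(NULL)
      start0 <- (seq_len(n) - 1L) * step
      tibble(
        window_id = sprintf("%s:%d-%d", id, start0 + 1L, start0 + width),
        contig_id = id,
        start0 = start0,
        end0 = start0 + width,
        length = width,
        sequence = substring(seq, start0 + 1L, start0 + width)
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Write windows as FASTA plus a window index TSV
#'
#' @param windows A window tibble from [make_windows()].
#' @param fasta_path,index_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_windows <- function(windows, fasta_path = NULL, index_path = NULL) {
  if (!is.null(fasta_path)) {
    dna <- Biostrings::DNAStringSet(
      setNames(windows$sequence, windows$window_id))
    Biostrings::writeXStringSet(dna, fasta_path)
  }
  if (!is.null(index_path)) {
    write_hashed_tsv(
      windows[, c("window_id", "contig_id", "start0", "end0")], index_path)
  }
  invisible(list(fasta = fasta_path, index = index_path))
}

#' Read a window index TSV
#'
#' @param path Path to a window index written by [write_windows()].
#' @return A tibble with `window_id`, `contig_id`, `start0`, `end0`,
#'   `length` columns (no sequences).
#' @export
read_window_index <- function(path) {
  x <- read_hashed_tsv(path,
                       c(window_id = "c", contig_id = "c",
                         start0 = "i", end0 = "i"))
  x$length <- x$end0 - x$start0
  x
}
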