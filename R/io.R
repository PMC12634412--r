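# Readers and writers for the standard formats the pipeline consumes and
# emits. All project TSVs carry a single '#'-prefixed header line, fixed
# column order, and '.' for undefined values.

write_hashed_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    col <- x[[j]]
    if (is.numeric(col)) col <- format(col, digits = 15, trim = TRUE,
                                       scientific = FALSE)
    col[is.na(x[[j]])] <- "."
    x[[j]] <- col
  }
  con <- file(path, "wb")  # binary mode: LF endings, byte-stable output
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0) {
    writeLines(do.call(paste, c(unname(as.list(x)), sep = "\t")), con)
  }
  invisible(path)
}

read_hashed_tsv <- function(path, col_spec) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  out <- if (length(body) == 0) {
    stats::setNames(rep(list(character()), length(header)), header)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    stats::setNames(
      lapply(seq_along(header), function(j) vapply(parts, `[[`, "", j)),
      header)
  }
  out <- tibble::as_tibble(out)
  for (nm in names(col_spec)) {
    if (!nm %in% names(out)) stop("missing column '", nm, "' in ", path)
    v <- out[[nm]]
    v[v == "."] <- NA
    out[[nm]] <- switch(col_spec[[nm]],
                        c = v, i = as.integer(v), d = as.numeric(v),
                        l = as.logical(v))
  }
  out
}

#' Parse a 12-column tabular alignment file
#'
#' Reads the standard 12-column tab-separated local-alignment table
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore) produced by blastn with tabular output.
#' Comment lines starting with `#` are skipped. Such a file can be supplied
#' to [run_pipeline()] in place of the internal aligner.
#'
#' @param path Path to the alignment table.
#' @return A tibble of alignment hits with the package's column names
#'   (`window_id`, `subject_contig_id`, `pct_identity`, `aln_length`,
#'   `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `evalue`, `score`).
#' @export
parse_alignment_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble(window_id = character(), subject_contig_id = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), score = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12)) {
    bad <- which(nfield != 12)[1]
    stop(sprintf("line %d of %s has %d columns; expected 12",
                 lineno[bad], path, nfield[bad]))
  }
  col <- function(j) vapply(parts, `[[`, "", j)
  tibble(
    window_id = col(1),
    subject_contig_id = col(2),
    pct_identity = as.numeric(col(3)),
    aln_length = as.integer(col(4)),
    mismatches = as.integer(col(5)),
    gap_opens = as.integer(col(6)),
    q_start = as.integer(col(7)),
    q_end = as.integer(col(8)),
    s_start = as.integer(col(9)),
    s_end = as.integer(col(10)),
    evalue = as.numeric(col(11)),
    score = as.numeric(col(12))
  )
}

#' Parse a per-base depth table
#'
#' Reads the 3-column output dialect of `samtools depth`: reference name,
#' 1-based position, depth. Positions absent from the table are treated as
#' depth 0 downstream.
#'
#' @param path Path to the depth TSV.
#' @return A tibble with columns `name`, `pos`, `depth`.
#' @export
parse_depth_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(name = character(), pos = integer(), depth = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("depth table must have exactly 3 tab-separated columns: ", path)
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  depth <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(pos) || anyNA(depth)) {
    stop("non-integer position or depth in ", path)
  }
  if (any(pos < 1)) stop("depth positions must be 1-based (found pos < 1)")
  tibble(name = vapply(parts, `[[`, "", 1), pos = pos, depth = depth)
}

#' Write a per-base depth table
#'
#' @param depth A tibble with `name`, `pos`, `depth` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(depth) > 0) {
    writeLines(paste(depth$name, depth$pos, depth$depth, sep = "\t"), con)
  }
  invisible(path)
}

#' Read SNP-relevant fields from a VCF file
#'
#' Extracts CHROM, POS, REF, ALT and QUAL from a VCF v4.x file. Only these
#' fields are consulted by [count_snps()].
#'
#' @param path Path to an uncompressed VCF.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @export
read_vcf_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric()))
  }
  tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
}

#' Write variant records as a minimal VCF v4.2 file
#'
#' @param variants A tibble with `chrom`, `pos`, `ref`, `alt` columns and
#'   optionally `qual` and `af` (allele frequency, emitted as `INFO/AF`).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">"
  ), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), contig_lengths), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants) > 0) {
    qual <- if ("qual" %in% names(variants)) {
      ifelse(is.na(variants$qual), ".", format(variants$qual))
    } else "."
    info <- if ("af" %in% names(variants)) {
      sprintf("AF=%s", format(variants$af, trim = TRUE))
    } else "."
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, qual, "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene annotations from a TSV
#'
#' The annotation dialect is: `gene_id`, `contig_id`, `start`, `end`
#' (1-based inclusive), `strand` (`+`/`-`), `gene_type` (`CDS`, `tRNA`,
#' `rRNA`), `cog_categories` (semicolon-joined single letters, possibly
#' empty / `.`).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of gene annotations.
#' @export
read_gene_annotations <- function(path) {
  x <- read_hashed_tsv(path, c(
    gene_id = "c", contig_id = "c", start = "i", end = "i",
    strand = "c", gene_type = "c", cog_categories = "c"))
  x$cog_categories[is.na(x$cog_categories)] <- ""
  x
}

#' Write gene annotations to a TSV
#'
#' @param genes A gene annotation tibble (see [read_gene_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path) {
  g <- genes[, c("gene_id", "contig_id", "start", "end", "strand",
                 "gene_type", "cog_categories")]
  g$cog_categories[!nzchar(g$cog_categories)] <- NA
  write_hashed_tsv(g, path)
}

#' Read contig-to-bin assignments
#'
#' Accepts a 2-column TSV (`contig_id`, `bin_id`); a `#`-prefixed header is
#' optional.
#'
#' @param path Path to the bin TSV.
#' @return A tibble with `contig_id`, `bin_id`.
#' @export
read_bin_assignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0 && any(lengths(parts) != 2)) {
    stop("bin assignment table must have exactly 2 columns: ", path)
  }
  x <- tibble(contig_id = vapply(parts, `[[`, "", 1),
              bin_id = vapply(parts, `[[`, "", 2))
  if (anyDuplicated(x$contig_id)) {
    stop("a contig is assigned to more than one bin in ", path)
  }
  x
}

#' Write contig-to-bin assignments
#' @param bins A tibble with `contig_id`, `bin_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_assignments <- function(bins, path) {
  write_hashed_tsv(bins[, c("contig_id", "bin_id")], path)
}

#' Write reads to a FASTQ file
#'
#' Qualities are constant (`I`, Q40): the simulator models substitution
#' errors directly, so per-base qualities carry no information.
#'
#' @param reads A tibble with `read_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_reads_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(dna)),
         sequence = unname(as.character(dna)))
}

#' Read read placements (read to reference interval) from a TSV
#'
#' Placements locate each read on the reference contigs and stand in for a
#' read mapping when selecting the reads that overlap a window. The dialect
#' is 4 columns: `read_id`, `contig_id`, `start`, `end` (1-based inclusive).
#'
#' @param path Path to the placements TSV.
#' @return A tibble with those four columns.
#' @export
read_placements <- function(path) {
  read_hashed_tsv(path, c(read_id = "c", contig_id = "c",
                          start = "i", end = "i"))
}

#' Write read placements to a TSV
#' @param placements A tibble with `read_id`, `contig_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  write_hashed_tsv(
    placements[, c("read_id", "contig_id", "start", "end")], path)
}
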