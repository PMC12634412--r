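Package: asmgaps
Title: Window-Level Evaluation of Short-Read Metagenome Assemblies
    Against Long-Read References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies where and why short-read metagenome assemblies
    fail relative to long-read reference contigs. Long-read contigs are
    split into fixed-width sliding windows; each window is scored for
    percent recovery by high-identity local alignment of short-read
    contigs, classified for cross-assembler consistency, and profiled
    with a compacted de Bruijn graph of the overlapping reads to measure
    local population diversity. Functional gene categories are tested
    for enrichment among poorly assembled windows with Fisher's exact
    test, and recovery is aggregated per genome bin. A synthetic
    community generator with planted coverage and strain-diversity
    structure and a toy unitig assembler allow the full pipeline to run
    end-to-end without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
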