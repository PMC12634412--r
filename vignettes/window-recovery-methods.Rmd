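---
title: "Methods: window-level recovery scoring of short-read assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-level recovery scoring of short-read assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmgaps)
```

## The evaluation model

`asmgaps` treats a long-read (LR) assembly as a per-region reference for a
short-read (SR) assembly of the same community. All scoring happens on
fixed-width windows of the LR contigs rather than on whole contigs, for two
reasons: contig length stops being a confounder of assembly consistency,
and every downstream statistic (percent recovery, graph size, enrichment
counts) compares like with like because every unit has the same length.

The pipeline stages, in order:

1. **Windowing.** Contigs are cut into windows of `width` bp every `step`
   bp (defaults 1000 / 500, i.e. 50% overlap). Trailing residue shorter
   than `width` is discarded so all windows are length-comparable; contigs
   shorter than one window contribute nothing and are counted in a log
   message. This assumes the LR contigs are trustworthy as local reference
   sequence — LR consensus errors are attributed to the SR assembly.
2. **Reference-set filter.** A window enters the analysis only if SR reads
   cover at least `min_breadth` (default 0.8) of its positions at depth
   `min_depth` or more (default 1×, so 800 bp of a 1 kb window). Windows
   failing this could not have been assembled for lack of data, and keeping
   them would conflate "no input" with "assembly failure". The boundary is
   inclusive: breadth exactly 0.8 is retained.
3. **Recovery.** Each window is aligned against each SR assembly; among
   local alignments with identity strictly greater than `min_identity`
   (default 99%), the longest is the best hit, and percent recovery is
   `100 * best_hit_length / window_length`, capped at 100. Alignment length
   counts columns (matches + mismatches + gaps), so 100% recovery requires
   a single (near-)full-length alignment — chains of partial hits do not
   count, which is the strict reading of a "best hit".
4. **Consistency.** For a designated pair of assemblies, equal nonzero
   best-hit lengths mean the window is consistently assembled (CA), unequal
   lengths not consistently assembled (NCA). Windows with no hit in either
   assembly form a separate `unassembled` class by default: equality of two
   zeros says nothing about assembler agreement, and folding those windows
   into CA would inflate it (a `zero_equal_ca` flag restores strict
   equality for users who want it).
5. **Graph metrics.** For each window, the compacted de Bruijn graph of the
   reads whose placement overlaps the window by at least 1 bp is built at
   `k = 31`; nodes sharing at least one canonical k-mer with the window are
   reference nodes; `graph_size` (total nodes) measures local population
   diversity and `surrounding_nodes` (non-reference nodes within graph
   distance `max_dist = 3` of any reference node, by multi-source BFS on
   the undirected node graph) measures how entangled the reference path is.
6. **Enrichment.** Genes are mapped to the window containing their midpoint
   and labeled fully / not fully assembled (per assembly, or `merged`:
   fully in *every* assembly). Per COG category, a two-sided Fisher exact
   test on the 2×2 table (in/out of category × fully/not fully) with
   Benjamini–Hochberg FDR across categories.
7. **Bin report.** Windows (with mean depth ≥ `min_cov`, default 1×)
   aggregate per genome bin into six cells — recovery length group 0–499 /
   500–999 / ≥1000 bp crossed with coverage class low/high — and bins are
   ranked by fraction fully recovered.

## The internal aligner

The package ships a seed-and-extend local aligner so the pipeline has no
external dependency; a precomputed 12-column tabular hit file from blastn
can be substituted anywhere (`hits_tsv` in `run_pipeline()`). Exact
15-mer seeds on both strands are clustered by diagonal (clusters merged
when their implied subject regions overlap) and each cluster is resolved by
a banded affine-gap Smith–Waterman with match +1, mismatch −2, and gap cost
5 + 2·length, a band padding of 32 diagonals around the seed range, and 50
bp of region padding. Identity is `100 · matches / columns`.

Numerical conventions that matter for reproducibility:

- **Ties between co-optimal alignments.** When several local alignments
  achieve the same optimal score (typically a substitution two positions
  from an alignment end, where trimming three columns changes the score by
  zero), the traceback prefers diagonal continuation and the latest
  highest-scoring cell, so the *longest* co-optimal alignment is reported
  deterministically. The test suite checks the aligner against a full
  Smith–Waterman oracle with the same scoring: scores must match exactly;
  length and identity must match whenever the optimum is unique.
- **Best-hit ties** across subjects are broken by higher identity, then
  lexicographically smallest subject id, so reruns are bit-identical.
- The identity threshold is strict (`> 99`, not `>= 99`), and a hit must
  span at least one seed length (15 columns).
- N bases never match anything, so they count as mismatches.

## The de Bruijn graph

K-mers are canonicalized as the lexicographic minimum of a k-mer and its
reverse complement; k must be odd (no self-reverse-complement k-mers) and
at most 63 (2-bit packing in a 128-bit word). Unitigs are maximal
non-branching paths of the bidirected graph; node coverage is the mean
multiplicity of the node's k-mers; edges record (k−1)-overlaps between
unitig ends with orientations, and `write_gfa()` / `read_gfa()` round-trip
the graph through GFA 1.0. Circular unitigs (a whole plasmid-like
component) are flagged.

`build_unitig_graph()` applies no abundance filter by default
(`min_count = 1`), as the primitive. The per-window analysis
(`window_graph_metrics()`, `run_pipeline()`) defaults to `min_count = 2`,
matching the abundance cutoff of the standard compacted-graph constructors:
with realistic substitution error rates, singleton error k-mers grow
linearly with depth and at a few hundred × contribute hundreds of noise
nodes per window in island and clean windows alike, reducing graph size to
a pure error statistic; dropping singletons leaves the strain-driven
structure. Reference-node flagging uses exact shared canonical k-mers
rather than alignment: at k = 31 a shared k-mer implies ≥ 96.8% local
identity over its span, and the criterion is deterministic. Distance for
`surrounding_nodes` ignores orientation, matching what graph viewers
display as "nodes"; both k and the distance cutoff are parameters, since
upstream tools do not pin them down.

## Statistics

- **Mann–Whitney U** (`mw_u_test()`, used by `snp_group_test()` and the
  island comparisons): when both groups have fewer than 20 observations the
  two-sided p-value comes from the exact conditional distribution of U
  given the observed midranks (a generating-function dynamic program over
  doubled ranks, so ties are exact); otherwise the normal approximation
  with tie correction and no continuity correction. `stats::wilcox.test`
  refuses exact computation under ties, which is why the test is
  implemented in the package; the approximation path is cross-checked
  against `wilcox.test(correct = FALSE)` and the exact path against brute
  enumeration in the test suite. The test choice itself is a package
  decision (counts are non-normal); it is isolated behind
  `snp_group_test()` and swappable.
- **Fisher + FDR**: `stats::fisher.test` (two-sided) and
  `stats::p.adjust(method = "BH")`; the suite verifies both against
  exhaustive hypergeometric enumeration and the step-up rule. The reported
  odds ratio is the sample odds ratio `ad/bc` (not the conditional MLE), so
  its side of 1 gives the enrichment direction; `direction` is only
  assigned to categories with q below `alpha`.
- Genes carrying several COG letters count once per letter (standard COG
  practice); the complement cells count each gene once. Midpoint
  assignment puts each gene in exactly one window (ties to the earlier
  window), avoiding double counting across the 500 bp overlap zones.

## The synthetic community

The generator plants exactly the structure the pipeline is meant to
detect, with defaults chosen once as field-realistic values:

| parameter | default | meaning |
|---|---|---|
| `n_genomes`, `genome_length` | 3 × 50 kb | community size (desk-scale) |
| `abundance_mu`, `abundance_sigma` | 0, 0.5 | lognormal abundances |
| `islands_per_genome`, `island_length` | 1 × 5 kb | diversity islands |
| `island_snp_density` | 0.01 /bp | strain SNPs inside islands |
| `background_snp_density` | 0 | strain SNPs elsewhere |
| `minor_haplotype_freq` | 0.3 | minor strain frequency in the read pool |
| `read_length`, `error_rate` | 150 bp, 0.001 | single-end reads, substitution errors |
| `total_bases` | 30× genome total | sequencing effort |
| `mobile_cog_fraction_in_islands` | 0.8 | island genes carrying category X |
| `contig_margin` | 200 bp | genome ends trimmed off the reference contigs |
| `n_island_genomes` | all | genomes that carry islands |

Genomes are i.i.d. uniform DNA. Each genome has a major haplotype and one
minor haplotype whose substitutions are placed per-base at the island or
background density; islands are placed one per equal block of the contig
region (uniformly within the block), so they never overlap. The emitted
reference contigs are the major haplotypes trimmed by `contig_margin` at
both ends — the long-read stand-in deliberately excludes the genome ends,
where uniform read sampling gives sloping coverage and edge effects would
otherwise masquerade as assembly failure. Genes tile the contig region
with fixed length and alternating strand; island genes draw COG category
`X` with the configured probability, everything else draws uniformly from
a non-X alphabet, and a few tRNA (76 bp) and rRNA (1500 bp) genes per
genome are placed uniformly. Depth tables and the VCF are emitted from
read provenance (each read's true source interval), which preserves the
exact file formats of the mapping/variant-calling tools while removing the
external dependency.

The toy assembler emits every maximal non-branching path of the canonical
unitig graph as a contig, after dropping k-mers below `min_count` (2) *and*
below `cov_frac` (0.1) times the median multiplicity of the non-singleton
k-mer spectrum. The relative cutoff mirrors how real assemblers scale
their coverage cutoff with depth: without it, sequencing errors that recur
at the same position (likely at high depth even at a 10⁻³ error rate) are
indistinguishable from low-frequency strain variation and shatter contigs,
making recovery *decrease* with depth. Contigs are reported
strand-canonically (lexicographic minimum of the sequence and its reverse
complement) and sorted, so output is deterministic; running the assembler
at two k values (e.g. 21 and 41) yields two assemblers that genuinely
disagree at moderate depth, where bubble-arm k-mer dropout depends on k —
which is what makes the CA/NCA classification non-trivial on synthetic
data. At very high depth both k values break at identical SNP boundaries
and agree almost everywhere; real assembler pairs differ more than that.

What the simulator does **not** emulate: paired-end reads (pairing adds
nothing to any implemented statistic), indel or quality-dependent
sequencing errors, chimeric reference contigs, inter-genome homology or
repeats, GC/composition bias, and assembler heuristics beyond unitig
construction. Passing tests therefore demonstrate that the pipeline's
statistics respond correctly to planted coverage and diversity structure —
not that any particular real assembler pair will show effects of the same
magnitude.

## Ground truth and evaluation conventions

Per-window truth marks a window as an island member when at least half of
it lies inside an island; boundary windows are diluted rather than
excluded, which makes island-versus-clean comparisons conservative.
Expected depth per window is the genome's expected interior depth
(abundance × reads × read length / genome length). In the enrichment
evaluation, planted-category specificity is judged direction-aware: the
planted category must be called enriched among not-fully-assembled genes
(q < 0.05), and no uniformly placed category may be called in that failure
direction — uniform categories can legitimately show counter-enrichment
toward the fully-assembled side, because a mobilome category concentrated
in islands depletes every other category there (a compositional effect,
not a false positive).

## Decisions where the design was open

- Contigs shorter than one window are dropped with a logged count.
- SNP counting applies no quality or depth filter by default
  (`min_qual = 0`); planted VCFs have no meaningful QUAL and real callers
  differ too much for one default to be right.
- SNPs in window overlap zones increment both windows: each window is an
  independent scoring unit.
- The low/high coverage boundary in the bin report defaults to 10× (the
  boundary value itself is "high"), with `cov_threshold` exposed because
  20× is an equally defensible choice and published descriptions disagree;
  both are supported and neither is asserted as canonical.
- Depth tables may name windows or contigs; both dialects are accepted and
  projected onto windows. Positions beyond a window's length are hard
  errors; contig-level positions can only be validated when contig lengths
  are supplied (as `run_pipeline()` does), since the window index alone
  does not bound a contig.
- Reads are selected for a window's graph by ≥ 1 bp placement overlap;
  placements come from a TSV (or simulator provenance), since the package
  deliberately implements no read mapper.

## Problem sizes

The test suite and the acceptance script run communities of 2–12 genomes
of 15–50 kb at 1–200× depth (up to ~80 000 reads and ~120 windows per
condition). These sizes give every comparison at least 50 windows or 300
genes per group while keeping a full run in the order of a minute; all
statistics scale linearly in windows and reads.

## Known limitations

- The aligner assumes near-identical hits (it seeds with exact 15-mers and
  a ±32 diagonal band), which is appropriate for the >99% identity regime
  but not a general-purpose aligner.
- `percent_recovery` uses alignment columns, so a gapped full-span
  alignment can reach 100% with small indels; this matches the tabular
  convention of the standard aligner output it mirrors.
- More than two assembly labels are accepted, but CA/NCA is defined for
  one designated pair; other labels get per-assembly metrics only.
- The exact Mann–Whitney path is quadratic in total rank sum and is
  reserved for both groups < 20; large unbalanced designs use the normal
  approximation.
- k is capped at 63 by the 128-bit k-mer packing.
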