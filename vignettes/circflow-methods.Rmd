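---
title: "Methods: back-splice junction discovery and circRNA characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: back-splice junction discovery and circRNA characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

circflow implements a complete desk-scale workflow for discovering and
characterizing circular RNAs (circRNAs) from rRNA-depleted, RNase R-treated
RNA-seq: two independent back-splice callers with per-sample consensus,
junction classification and alternative-circularization summaries,
junction-read quantification and differential expression, co-expression
with parental genes and module eigengenes, miRNA sponge-site scanning, and
convergent/divergent primer design with in-silico PCR. This vignette
explains the models and the numerical choices; the README shows the
end-to-end call sequence.

## The evidence model: back-splice junction reads

A circRNA arises when a downstream 5' splice donor joins an upstream 3'
acceptor, producing a covalently closed circle. In short-read data the only
direct evidence is the *junction read*: a read crossing the back-splice
point, which aligns as a two-segment chimera in reversed genomic order (the
read's prefix maps downstream of its suffix). Junctions are written
`scaffold-start-end` with 1-based inclusive coordinates, `start` the first
and `end` the last base inside the circle. BED-style exports would convert
to 0-based half-open; everything internal stays 1-based.

### The split-segment caller

`detect_split()` anchors the first and last `anchor` nt of each read (both
orientations) by exact k-mer matching against the scaffolds, extends each
anchor without gaps, and calls a junction `(start, end)` when the prefix
segment ends at `end`, the suffix segment starts at `start` upstream of the
prefix, both segments are at least `anchor` nt, and the implied circle is
at most `max_span`. Reads that extend colinearly over their full length are
linear and ignored; reads whose anchors support more than one junction are
dropped as ambiguous. Junctions with fewer than `min_reads` (default 2)
junction reads in a sample are discarded — the standard retention rule for
circRNA catalogs.

Defaults: `anchor = 20` nt, `max_mismatch = 2` (realignment caller),
`max_span = 100` kb. Published catalogs inherit these from aligner
defaults without stating them; here they are explicit parameters chosen
for exactness at desk scale, and they are echoed in output headers through
the function signatures. The mapper is exact k-mer anchoring plus ungapped
extension — entirely adequate for the synthetic error model, and
deliberately not a general-purpose spliced aligner.

### The realignment caller

`detect_realign()` is the second, overlapping-but-distinct line of
evidence. Its candidate set is the split caller's junctions pooled across
samples *plus every annotated exon-boundary pair* within `max_span`. For
each candidate it builds a junction pseudo-reference (the circle's last
`read_len - anchor` nt followed by its first `read_len - anchor` nt,
exon-spliced for exonic candidates) and counts reads that align across the
midpoint with at least `anchor` nt on each side and at most `max_mismatch`
mismatches. Reads are located by exact matching of the junction-centered
`2 x anchor`-mer, then verified by full ungapped comparison; a read whose
sequencing errors fall inside that seed can be missed, which is an accepted
property of the seed-and-extend design.

### Consensus and catalogs

`intersect_callers()` keeps junctions called by both callers in the same
sample at identical coordinates (a `--slop`-style tolerance exists for real
data but defaults to 0 because the simulator is exact) and reports
|A|, |B|, |A∩B|, |A∪B| and the intersection/union ratio per sample. The
consensus junction-read count is taken from the realignment caller, which
counts against the junction sequence directly; a `max` policy is
selectable. `merge_samples()` unions per-sample consensus sets by
coordinates into a cross-sample catalog with zero-filled per-sample counts,
and `sharing_stats()` produces replicate- and tissue-level sharing
percentages plus 2- and 3-set Venn region counts. Deduplication across
samples is by coordinates alone, not strand: split reads do not observe the
transcribed strand, so strand is assigned later from the parent gene.

## Classification and alternative circularization

`classify_junctions()` applies a three-class rule: a junction is **exonic**
when both ends overlap exons of a single gene (that gene becomes the
parent; intron-retaining circles whose ends are exonic fold into this
class, keeping three classes); otherwise **intronic** when the whole span
lies inside a single gene; otherwise **intergenic**. End overlap is exact
by default (`slop = 0`) and does not require splice-site equality — the
boundary tolerance is exposed rather than hard-coded because field practice
varies. If the two ends hit exons of two different genes and no single gene
covers both, the junction is demoted to intergenic with a warning. For
exonic circles the package reports the number of parent exons the span
overlaps and a position category computed in *transcript* orientation
(`first` = only the 5'-most exon, `last`, `middle`, `first_and_last`), so
minus-strand genes flip genomic order. `alternative_circularization()`
groups exonic circles by parent gene and tabulates how many genes produce
k = 1, 2, 3, ... circles.

## Quantification, differential expression, clustering

Expression of a circRNA is `RPM = junction reads / total reads x 1e6`;
parental genes use `FPKM = fragments / (exonic kb x mapped millions)` with
exonic length the merged exon span. Fold changes are ratios of
replicate-mean RPM with a pseudocount (default 0.01 RPM) guarding
zero-count features — the zero-handling rule is a package choice, stated
here because conventions differ.

P-values come from a two-sided conditional binomial test on pooled
junction reads: conditional on the pooled total `n = x_A + x_B`, under the
null `x_A ~ Binomial(n, pi0)` with `pi0` the A-share of the pooled library
size; the two-sided p is twice the smaller tail, capped at 1. Q-values are
Benjamini–Hochberg within each tissue pair, and a feature is called DE iff
`|log2FC| >= 1` *and* `q <= 0.05`. A dispersion-modelling
negative-binomial GLM is deliberately out of scope: junction-read counts
at desk scale are small, the exact conditional test is dependency-free and
well calibrated (the suite verifies <= 1% of 2,000 null features pass both
gates, and >= 90% power for 8-fold features with pooled counts >= 20), and
the fold-change gate makes the procedure conservative.

`zscore_cluster()` z-scores each feature's tissue-mean RPM profile,
clusters features and profiles hierarchically (Euclidean distance, average
linkage) and cuts the feature tree into `k` clusters labelled with Roman
numerals (ordered by first appearance in the dendrogram, so labels are
stable). Features with constant profiles carry no shape and are dropped
with a warning rather than silently producing NaN z-scores.

## Co-expression and enrichment

`pair_correlation()` computes Pearson r between each circRNA and its
parent gene across shared samples (two-sided t-test p on n-2 df),
classifying pairs at `r >= 0.5, p < 0.05` (positive) and `r <= -0.5`
(negative). Correlations use the replicate-level samples (the 3x3 = 9
layout) rather than tissue means — three points would make p-values
meaningless — and this is configurable by passing whatever sample set the
matrices share. Zero-variance profiles are flagged, not errored.

`module_correlation()` takes module membership as *input* (from WGCNA or
any other detection tool — module detection is not re-implemented, because
the quantity of interest here is the module-circRNA correlation, not the
clustering) and summarizes each module by its eigengene: the first right
singular vector of the gene-standardized expression, sign-oriented to
correlate positively with the module mean so the decomposition's arbitrary
sign cannot flip results between runs. circRNA-module pairs are classified
at the stricter `r >= 0.9, p < 0.05`.

`hypergeom_enrichment()` is a generic upper-tail hypergeometric test of a
query gene set against user-supplied term maps over an explicit background,
BH-corrected, with significance requiring `q < 0.05` *and* at least 3 query
genes in the term. No ontology topology is used.

## miRNA sponge-site scanning

`scan_targets()` slides each miRNA over each circle's linearized sequence,
padded with its own first `L-1` nt so sites spanning the back-splice are
found; wrap-around coordinates map back to the circle, with
`site_end < site_start` marking junction-spanning sites. Each window is
scored by an additive complementarity penalty (the *expectation*; lower is
better): Watson–Crick match 0, G:U wobble 0.5, mismatch 1, gap 2, doubled
when the miRNA position (5'-anchored) lies in the core region 2–13, with
at most one gap per site, tried only when the gapless score fails the
cutoff (default 5.0). Overlapping windows collapse to the best-scoring
site, ties to the leftmost.

This penalty table is an explicit, reproducible scheme in the style of
plant small-RNA target servers; absolute hit lists from any such scheme are
scheme-dependent, and the RNA-accessibility (energy) component of server
pipelines is intentionally not reproduced here, so hit lists should be read
as complementarity candidates, not validated interactions.
`sponge_summary()` reduces hits to per-miRNA and per-circRNA multiplicity
tables, duplicates counted once per pair, ties broken lexicographically.

## Primer design and in-silico PCR

For each circle `design_primers()` returns a convergent and a divergent
pair (18–24 nt, Wallace-rule Tm `2(A+T) + 4(G+C)`, pair ΔTm <= 4 °C,
target product 100–400 bp on the circular cDNA), refusing circles under
80 nt. Primers are placed fully inside single exon segments so both
primers also bind the genome. The divergent pair flanks the back-splice
(forward primer near the circle's 3' end, reverse near its 5' start): on
the circular cDNA its product crosses the junction; on the linear genome
the pair faces outward and yields nothing — the defining validation
signature. The convergent pair faces inward; for multi-exon circles it is
placed to straddle the first intron, so the genomic product is strictly
longer than the cDNA product, reproducing the size-shift signature;
single-segment circles give equal sizes, as no intron intervenes.
`insilico_pcr()` is an exact-match, both-strand amplicon enumerator (<= 5
kb, circular templates searched across the origin) used to verify every
designed pair.

## The synthetic-data generator

The generator defines the study conditions all tests run under:

* **Genome** (`simulate_genome()`): by default 5 scaffolds x 50 kb of
  uniform random A/C/G/T, 30 genes placed round-robin with >= 500 nt
  intergenic gaps, 3–8 exons of 80–250 nt separated by introns of 150–500
  nt, random strands. These sizes keep every stage exact and fast while
  leaving room for all three circRNA classes; real plant genomes'
  repetitive content and composition bias are *not* emulated, so mapping
  unambiguity here is better than in real data.
* **Planted circles** (`plant_circrnas()`): exonic circles span 1–5
  consecutive exons with ends on exon boundaries, intronic circles sit
  strictly inside introns, intergenic circles inside gene-free gaps; all
  at least 150 nt (the read length) so junction reads never wrap twice.
  Each circle draws a log-normal base abundance (meanlog `log(8)`, sdlog
  0.4 — a handful of junction reads per library, the regime tissue
  catalogs report). Because a back-splice breakpoint is genomically
  ambiguous under junction-flanking microhomology, the generator adjusts
  at most two bases just *outside* each circle (never inside an exon) so
  every planted junction has a unique representation; candidate circles
  whose shared boundary positions cannot all be disambiguated are skipped
  during placement.
* **Design** (`sample_design()`): 3 tissues (leaf, root, stem) x 3
  replicates; tissue abundance multipliers default to leaf 1x, root 4x,
  stem 2x (root-dominant material, as in root-accumulating medicinal
  plants). Note the multiplier scales junction reads and library size
  together, so per-feature RPM is nearly multiplier-invariant — a
  composition effect the DE calibration therefore probes with explicitly
  planted per-feature fold changes instead; junction-read counts are
  negative-binomial with variance
  `mu + phi mu^2`, `phi = 0.2` (typical bulk RNA-seq overdispersion;
  `phi = 0` gives Poisson). RNase R is modelled purely as a linear-read
  retention fraction (default 0.05) — no degradation kinetics. An
  optional `min_junction_reads` floor guarantees minimum junction coverage
  per expressed sample for validation designs that require it; it defaults
  to 0.
* **Reads** (`simulate_reads()`): 2 x 150 nt pairs; mate 1 of a junction
  pair crosses the back-splice with >= 20 nt on each side, with both
  genomic anchors confined to the junction-flanking exons so a two-segment
  aligner can detect them (three-segment chimeras are out of scope); mate
  2 samples a non-crossing window. Linear reads sample spliced
  transcripts. Errors are uniform substitutions (<= 5%); correct bases get
  Q37 and error bases Q12, which makes the Q20/50% and N/5% QC rules
  testable. No instrument error profiles, PCR duplicates or rRNA reads are
  simulated.

Passing tests on this generator demonstrate algorithmic correctness —
exact recovery, calibration, set algebra — not performance on real
libraries, where repeats, partial degradation and alignment ambiguity
dominate.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and is byte-deterministic
given it. The validation suite runs the full pipeline on a 250 kb genome
with 30 planted circles and nine libraries (a few thousand read pairs per
library), 1,000-junction classification oracles, 2,000-feature null
calibrations, 500-replicate correlation recovery and 100 planted
junction-spanning miRNA sites — sizes chosen so each property is measured
with comfortable margins while the whole suite stays interactive.

## Known limitations

* The callers assume two-segment chimeras with exact anchors; they are not
  aligners for real, indel-containing reads.
* Consensus matching at 0 nt tolerance is correct for the simulator;
  real-data use should set a small `slop`.
* The conditional binomial DE test ignores biological replicate
  overdispersion beyond what pooling absorbs; it is exact and calibrated
  for the simulated regime but will be anticonservative for strongly
  overdispersed real replicates.
* The miRNA penalty scheme is a documented stand-in for server-side
  scoring; absolute expectation values are not comparable across schemes.
* Tm is Wallace-rule only; no nearest-neighbor thermodynamics, dimer or
  hairpin screening.
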