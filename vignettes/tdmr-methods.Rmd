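---
title: "Methods: associating tissue-specific methylation with expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating tissue-specific methylation with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmr)
```

## The question and the model

DNA methylation is classically a repressive mark: more methylation at a
gene, less expression. Comparing two tissues, however, a substantial
minority of tissue-specific differentially methylated regions (T-DMRs)
move *with* expression rather than against it. This package implements
the analysis that quantifies and characterizes that split.

The core quantity is a pair (T-DMR, gene) with two differences taken in
a fixed tissue order: ΔM, the methylation difference of the region, and
ΔE, the difference of mean log2 expression of the gene. A pair is
**positive** when sign(ΔM) = sign(ΔE), **negative** when the signs
oppose, and **excluded** when |ΔE| ≤ log2(1.25) (below a 25% fold
change the sign of ΔE is not trusted) or when either difference is
exactly zero. Everything downstream — the shuffle nulls, the coherence
test, the context comparisons, the motif discovery — conditions on this
classification.

Pairing is proximity-first: a DMR is paired with every gene whose
window from 4 kb upstream of the strand-resolved TSS to the
transcription end it overlaps by at least one base. DMRs can
additionally be paired distally through a user-supplied
enhancer–promoter map; a distal pair duplicating an existing proximal
pair is dropped. Because windows of neighbouring genes can overlap, one
DMR may pair with several genes; summaries therefore report fractions
both over pairs and over unique DMRs (deduplicated by majority sign,
ties dropped).

## Null models

Three permutation nulls are used, all seeded and deterministic:

* **Sign-split expectation.** ΔM values are permuted across all pairs
  while each pair's ΔE stays put; the positive/negative fractions are
  recomputed per shuffle under the identical |ΔE| filter. For
  independent signs the expectation approaches
  p·q + (1−p)(1−q), where p and q are the marginal positive-sign
  fractions of ΔM and ΔE.
* **Coherence.** Genes with ≥2 non-excluded pairs are kept; the
  multiset of their ΔM values is permuted over those DMR slots only
  (the closest reading of a shuffle "across these genes"), each pair's
  sign is recomputed against its gene's own ΔE, and genes are
  re-counted as coherent-positive, coherent-negative or incoherent.
  Observed counts are scored as `Z = (n − S̄)/std(S)` with the sample
  standard deviation over (by default) 10,000 shuffles; at that depth
  the sample-vs-population distinction is negligible. A degenerate null
  (all ΔM one sign) yields a flagged undefined Z, never an infinity.
  Under a random-sign null a gene with k DMRs is coherent with
  probability q^k + (1−q)^k, which the null means reproduce within
  Monte-Carlo error.
* **DHS placement.** The observed fraction of DMRs overlapping a DHS
  peak is compared with length-preserving uniform random placements
  inside the probe space (the array-assayable intervals, merged). The
  p-value is the exact binomial tail of the observed count at the
  null's mean per-DMR rate — upper tail for enrichment, lower for
  depletion.

Exact tails are used throughout: binomial via the regularized
incomplete beta, hypergeometric for set enrichment, never a normal
approximation or continuity correction. All enrichment tests use the
inclusive upper-tail convention P(X ≥ k). Two location-category
proportions are compared by a one-sided binomial test of the first
class against the second class's proportion as a fixed reference — the
second set is the reference because the comparison is asymmetric by
construction; this is one of two defensible readings of a "binomial
model" comparison and is stated here as the package's choice.

## Genomic context

Every DMR receives exactly one feature category from its midpoint with
precedence exon > intron > upstream > downstream > intergenic
(gene-body wins over a neighbour's flank; flanks default to 4 kb and
are strand-aware). Midpoint assignment forces mutual exclusivity even
for DMRs straddling features. The category set is deliberately the
five-way one; finer promoter subcategories (first exon / 5' UTR) can be
layered on by the user but are not built in.

DHS calling from replicates uses a k-of-n coverage rule per tissue
(e.g. "3 of 7"); a tissue's DHS overlapping the other tissue's DHS by
≥1 bp is *shared* (shared regions merged), the rest are
tissue-specific. "Within a DHS" means ≥1 bp overlap, not containment.

Conservation is summarized as the ECDF of per-CpG scores on a fixed
101-point grid over [0, 1] — plot-stable and resolution-independent; a
pointwise-lower curve is the more conserved class. The CpG
observed/expected ratio of a sequence is (n_CpG · L)/(n_C · n_G) with
overlapping CG counts on the given strand; non-ACGT positions are
skipped in all counts and a zero denominator yields a flagged NA. The
length normalization follows the standard observed/expected definition.

## Motif discovery

All 4^6 = 4,096 6-mers are enumerated (no reverse-complement
collapsing: the CpG-census figure of 1,185 CpG-containing 6-mers —
28.93% — is over raw words, implying no canonicalization). Occurrences
are counted overlapping, on the given strand, summed over sequences;
windows containing ambiguous bases are excluded from both numerator and
denominator. The background is sampled from gene windows at 10× depth
with each target length reused exactly ten times, so the length
distribution matches by construction. Each 6-mer's target count is
tested with the exact binomial upper tail at the background's pooled
per-position rate, FDR-corrected over all 4,096 motifs (thresholds
default to 1% for an all-DMR analysis and 5% for a DHS-restricted one).
The log2 enrichment score adds a 0.5 pseudocount on both sides for
plotting only — the test itself stays exact. Motifs significant in both
the negative and positive analyses are "dual".

Consistency between two analyses (e.g. all DMRs vs DHS-restricted) is
scored against a null drawing both significant sets uniformly without
replacement from the 4,096-motif universe with role proportions
preserved. For set sizes a and b the expected overlap is a·b/4096 —
about 6.7 for sizes 358 and 77. Published analyses of this design have
reported larger expected overlaps (13 for those sizes), implying a
different, unstated null; the uniform null is used here and the
discrepancy is documented rather than resolved.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_tdmr_study()`
produces a self-consistent dataset with truth tables for every planted
effect. Defaults emulate the targeted study design: 2,498 DMRs of
200–2,000 bp, 34% of informative pairs positive, expression in
triplicate vs duplicate with 0.2 sd log2 replicate noise, an 18%
DMR–DHS overlap against a 13% random-placement rate, and one planted
CpG-containing motif in the positive class and one CpG-free motif in
the negative class. Values the design does not pin down were chosen
once as field-plausible: 2,400 genes of 6–14 kb on two chromosomes
with 2–6 kb intergenic gaps (enough windows for mostly-single DMR
placement), 42% GC, 12% multi-DMR genes carrying 2–4 DMRs with a 0.9
coherence bias, 15% of DMR genes below the fold-change threshold to
exercise the filter, 5% distal DMRs wired through generated enhancers,
|ΔM| floored at 0.1 so a planted sign is never ambiguous at zero noise,
and |ΔE| floored at log2(1.25) for informative genes.

Two generator choices deserve emphasis:

* Methylation is generated directly as per-tissue levels in [0, 1];
  no probe-level array signal is simulated, because the pipeline
  consumes regions, not probes.
* `dhs_cover_frac` is the *null placement rate*: the generator
  calibrates the peak count so that a random length-preserving
  placement hits a peak with that probability
  (n_peaks ≈ rate · positions / (W̄ + L̄ − 1)). Raw base coverage
  would understate the null because an interval query overlaps a peak
  it merely touches; with 200–2,000 bp DMRs that inflation is several
  percentage points. Peaks are placed on a planted fraction of DMRs and
  avoid all others, so the realized overlap equals the planted
  fraction up to the rare cases where gene windows overlap; the truth
  table records both the planted flag and the realized overlap.

Motifs are planted by overwriting bases at uniform positions (never
insertion), preserving the length distribution the background sampler
matches. Per-CpG conservation scores are Normal draws clipped to
[0, 1] with class-dependent mean shifts (positive > negative >
background).

What the generator does *not* emulate: realistic chromatin landscape or
sequence composition (the genome is i.i.d. at fixed GC), probe-level
array artifacts, correlated replicate noise, overlapping genes or
isoforms, and biologically structured GO annotations. Passing tests
therefore demonstrate that the statistics recover planted effects under
the stated noise model — not that any particular biological dataset
will show those effects.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GTF input is converted
  on read, the only 1-based arithmetic in the package.
* Tissue order is fixed by the caller; ΔM and ΔE are always
  tissue1 − tissue2, so only sign agreement matters, not direction.
* Expression input may be linear or log2; the |ΔE| filter presumes the
  log2 scale (the threshold is log2(1.25)), so linear input must be
  read with `log_transform = TRUE`. Replicates aggregate by arithmetic
  mean of log2 values.
* Zero background rate for a motif with a nonzero target count gives
  p = 0 and a boundary flag; empty conservation classes are omitted
  with a warning; all-excluded pair sets and empty motif lists are
  errors.
* Problem sizes in the test suite are scaled to the structure of each
  check: kernel oracles run exhaustively to n = 20; recovery and
  direction checks use 10–20 seeds at 500–2,500 DMRs; shuffle-null
  calibrations use 10,000 shuffles where a closed form is compared and
  1,000 where only a direction is asserted.

## Interfaces

Readers cover BED3+ (extra columns preserved), BED12 and GTF gene
models, narrowPeak, bedGraph, FASTA (via Biostrings), and TSV tables
for expression (replicate columns per tissue), enhancer→gene maps and
gene→term annotations. All analysis functions take tibbles and return
tibbles; shuffle tests return small S3 objects with `tidy()`,
`glance()`, `print()` and (for the coherence test) `autoplot()`
methods. `plot_sign_scatter()`, `plot_conservation_ecdf()` and
`plot_motif_volcano()` cover the standard figures. The package is a
library, not a shell tool: scripted use goes through these functions,
as `scripts/acceptance.R` demonstrates end to end.

## Known limitations

* DMR calling, array normalization and enhancer prediction are out of
  scope; DMRs, probe space and the enhancer map are inputs.
* Motif matching against TF databases (and methylation-aware binding
  models) is not included; discovered 6-mers are reported as words.
* The coherence shuffle assumes exchangeable ΔM across multi-DMR
  genes; intra-gene correlation of methylation beyond the planted
  coherence is not modelled.
* With heavily overlapping gene windows a DMR contributes pairs to
  several genes; the unique-DMR summary resolves this by majority sign
  and drops ties, which slightly under-counts balanced cases.
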