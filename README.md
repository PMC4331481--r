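# tdmr

Tools for asking how tissue-specific differential DNA methylation
relates to gene expression. Given a set of tissue-specific
differentially methylated regions (T-DMRs) with per-tissue methylation
levels, replicate expression data for the same two tissues, gene
models, and optional DHS peaks, conservation scores and an
enhancer–promoter map, the package:

- pairs each T-DMR with genes, proximally (any overlap with the window
  from 4 kb upstream of the TSS to the transcription end) or distally
  (through an enhancer–promoter map), and classifies each pair as
  **positive** (ΔM and ΔE share a sign), **negative** (opposite signs),
  or **excluded** (|ΔE| ≤ log2(1.25)), where ΔM is the between-tissue
  methylation difference and ΔE the difference of mean log2 expression;
- estimates the expected sign split by permuting ΔM across pairs, and
  tests whether genes carrying multiple T-DMRs are *coherent* (all pairs
  share one sign relation) more or less often than a ΔM-shuffling null,
  scored as `Z = (n − S̄)/std(S)` over 10,000 shuffles;
- characterizes genomic context: feature categories by midpoint
  precedence (exon > intron > upstream > downstream > intergenic), DHS
  overlap enrichment against length-preserving random placement in the
  assayable probe space, conservation score ECDFs of CpG sites per
  class, and the CpG observed/expected ratio
  `(n_CpG · L)/(n_C · n_G)`;
- runs hypergeometric gene-set (GO term) enrichment with Bonferroni
  correction, and discovers 6-mers differentially enriched in positive
  vs negative T-DMR sequences with exact binomial tests against a
  10×, length-matched random background, Benjamini–Hochberg FDR, and
  positive/negative/dual role classification;
- ships a synthetic-data generator (`sim_config()`,
  `simulate_tdmr_study()`) that plants every effect the pipeline
  measures — sign-concordant fractions, coherent multi-DMR genes, DHS
  overlap, conservation shifts, spiked motifs — with truth tables, so
  every stage is testable without any external download.

All user-facing functions take a data frame first and return tibbles;
shuffle-test results support `tidy()`/`glance()` and `autoplot()`.

## Worked example

```r
library(tdmr)
library(dplyr)

cfg <- sim_config(n_genes = 600, n_dmrs = 500, seed = 42)
sim <- simulate_tdmr_study(cfg, sequences = FALSE)

pairs <- assign_proximal(sim$dmrs, sim$genes) |>
  classify_sign(sim$expression)
sign_fraction_summary(pairs) |>
  filter(unit == "pairs", proximity == "proximal")
#> # A tibble: 3 × 5
#>   proximity sign_class     n unit  fraction
#>   <chr>     <chr>      <int> <chr>    <dbl>
#> 1 proximal  excluded     101 pairs     NA
#> 2 proximal  negative     324 pairs      0.6
#> 3 proximal  positive     216 pairs      0.4
```

60% of informative pairs are negative (methylation up, expression
down) and 40% positive, close to the generator's planted 34% positive
share once incidental pairs from overlapping gene windows are mixed in;
101 pairs fall inside the 25% fold-change band and are excluded.

```r
coherence_null_test(pairs, n_shuffles = 2000, seed = 1)
#> Coherence shuffle test: 123 multi-DMR genes, 2000 shuffles
#> # A tibble: 3 × 7
#>   coherence_class   observed null_mean null_sd     z z_defined n_shuffles
#> 1 incoherent              44      75.5    5.15 -6.11 TRUE            2000
#> 2 coherent_negative       48      24.0    4.16  5.78 TRUE            2000
#> 3 coherent_positive       31      23.6    4.29  1.74 TRUE            2000
```

Genes with several T-DMRs are incoherent far less often than the
shuffle null expects (44 observed vs 75.5, Z = −6.1) and
coherent-negative far more often (Z = +5.8) — the generator planted a
90% coherence bias, and the test recovers it.

```r
dhs_overlap_enrichment(sim$dmrs, sim$dhs$peaks, sim$dhs$probe_space,
  n_shuffles = 200, seed = 1)
#> DHS overlap: observed 18.2% vs expected 12.1% (n = 500 DMRs), enrichment p = 4.87e-05
```

18% of DMRs sit in a DHS peak where random placement expects ~12% —
the planted open-chromatin enrichment.

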