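# stemFEA

Identification and characterization of quiescent, stem-like cell
populations in single-cell RNA-seq, and association of their gene
signatures with patient outcome.

Breast cancer stem cells (BCSCs) are rare, therapy-resistant,
tumor-initiating cells. Mammosphere culture enriches for them, and
single-cell RNA-seq of mammospheres typically reveals a small, quiescent,
stem-like cluster. `stemFEA` packages the statistical workflow used to
find and validate such populations, for computational biologists
analyzing 10x-style count matrices or bulk cohort exports:

- **Per-cell signature scoring**: after depth normalization
  (log1p of counts scaled to 10^4 per cell) and gene-wise z-scaling, a
  cell's score for a gene signature is the mean of its z-scores over the
  signature genes.
- **ROC-AUC enrichment** of a signature in a cluster, via the
  Mann–Whitney identity
  AUC = (R_in − n_in(n_in+1)/2) / (n_in·n_out) with midranks;
  *enriched* ⇔ AUC > 0.6 and two-sided Wilcoxon rank-sum P < 0.01
  (exact enumeration for ≤ 20 cells, tie-corrected normal otherwise).
- **Cluster signature derivation** from differentially expressed genes
  (rank-sum test, BH-adjusted P < 0.05, log2FC > 0.25, min 10%
  expressed), plus GMT I/O and signature overlap reports.
- **Cell-cycle scoring and regression**: S/G2M scores against
  expression-matched control genes; G1 ⇔ both scores ≤ 0; per-gene
  least-squares residualization on the two scores to remove
  proliferation signal.
- **Pathway-activity classes**: four-way per-cell classification
  (dual-negative / a-active / b-active / dual-positive) from two
  signature scores — the computational analog of dual-reporter sorting —
  with cluster abundance and marker-expression reports.
- **Cohort stratification**: tumors are signature-positive when ≥ 1
  signature gene has expression z ≥ 2 SD; groups compared by chi-squared
  (grade, subtype), log-rank (relapse-free and overall survival) and
  Welch t-tests on the mean signature z-score.
- **Limiting-dilution analysis (ELDA-style)**: single-hit Poisson model
  P(response | dose d) = 1 − exp(−f·d), fitted as a binomial GLM with
  complementary log-log link and offset log d; Wald 95% CI on log f,
  saturation-aware bounds, and likelihood-ratio group comparison.
- **A synthetic-data generator** (negative-binomial counts with planted
  programs, QC-failure cells, proliferation/quiescence structure,
  survival cohorts with planted hazard ratios, single-hit dilution
  outcomes) that makes every stage testable without downloads.

## Worked example

Simulate a 4-cluster experiment with one planted 50-gene stem-like
program (2 log2 fold in cluster 1) plus planted QC failures, then run QC,
normalization, clustering and enrichment:

```r
library(stemFEA)

cfg <- simConfig(nCells = 1000, nClusters = 4, qcMinGenes = 800,
                 nLowdepthCells = 20, nHighmitoCells = 10, seed = 1)
sce <- simulateCounts(cfg)
sce <- qcFilter(sce, minGenes = 800, maxMitoFrac = 0.15)
S4Vectors::metadata(sce)$qc_report
#>     reason   n
#> 1 lowdepth  20
#> 2 highmito  10
#> 3  doublet   0
#> 4  removed  30
#> 5 retained 970

sce <- clusterCells(scaleGenes(normalizeLog(sce)), nClusters = 4, seed = 1)
enrichmentTable(sce, plantedSignatures(sce))
#>   signature cluster   auc   p_value      bh_p enriched n_in n_out
#> 1     prog1       0 0.391  9.84e-09  9.84e-09    FALSE  384   586
#> 2     prog1       1 0.999 3.78e-124 1.51e-123     TRUE  255   715
#> 3     prog1       2 0.224  1.23e-32  2.45e-32    FALSE  194   776
#> 4     prog1       3 0.281  1.74e-16  2.32e-16    FALSE  137   833
```

The planted QC failures are removed exactly, and the enrichment rule
(AUC > 0.6 ∧ P < 0.01) fires for the carrier cluster only: the planted
program separates its cluster almost perfectly (AUC 0.999), while the
other clusters sit below 0.5 (their cells score *lower* than the rest,
which contains the carrier cluster).

Limiting-dilution frequency from a dose–response table:

```r
estimateFrequency(data.frame(dose = c(100, 1000, 10000),
                             tested = 6, response = c(1, 4, 6)))
#> LDAEstimate
#>   frequency: 0.001203 (1/831.4)
#>   95% CI: [0.000473, 0.003058]  (1/327 - 1/2,114.1)
```

One active (tumor-initiating) cell per ~831 cells, with the Wald interval
on the log scale. Saturated designs (all or no wells responding) are
flagged and reported as one-sided 95% bounds; `compareFrequencies()`
tests frequency differences between groups by a likelihood-ratio
chi-squared test.

`runPipeline()` chains QC → normalize → scale → cluster → cell-cycle
scoring/regression → enrichment → signature derivation → classification
from one declarative config (R list or YAML) and stamps every output
table with a provenance header (config hash, seed, package version). See
the vignette in `vignettes/signature-enrichment.Rmd` for the model
details, parameter meanings and design decisions.

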