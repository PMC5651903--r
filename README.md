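# PERKsig

Tools for deriving a cancer-specific pathway signature from tumor/normal
expression data and linking it to outcome, built around the analysis used
to define the cancer-specific PERK set (CSPS) in breast cancer and to
connect it — through its transcription factor CREB3L1 — to metastasis.

The package is aimed at computational biologists who want each stage of
that analysis as a tested, reusable component:

* **Signature derivation** — per-gene two-sided Student *t*-tests on
  `log2(x + 1)` tumor-versus-normal expression; the signature is the genes
  with `log2` fold change (difference of log-means) at least 1 *and*
  p-value below the Bonferroni-corrected 0.05 threshold.
* **Scoring & stratification** — sample score = mean `log2(x + 1)` over
  signature genes; deterministic top/bottom-tertile, top-half,
  33-percentile, and nested two-level binning.
* **Survival** — Kaplan–Meier curves, the two-group log-rank test
  (statistic `(O - E)^2 / V` on 1 df), and the Mantel–Haenszel hazard
  ratio `HR = (O1/E1)/(O2/E2)` with CI `exp(log HR ± 1.96·sqrt(1/E1 + 1/E2))`,
  after restricting follow-up to 120 months.
* **Enrichment** — preranked GSEA (signal-to-noise ranking
  `(m1−m2)/(s1+s2+ε)`, weighted-KS enrichment score, permutation NES and
  pooled-NES FDR) and the hypergeometric over-representation test.
* **ChIP binding** — closest-TSS peak annotation (summit anchor, lower-TSS
  tie rule), bound-gene calling, exact one-sided binomial enrichment
  `P(X ≥ k | n, p0)` against the genome-wide background rate, and direct
  H3K27ac co-localization of peaks.
* **CTC calibration** — OLS standard curve of spike-in luminescence on
  cell count, inverted into circulating-tumor-cell counts per ml.
* **Synthetic data** — generators for every stage with planted ground
  truth (planted overexpressed genes, a true hazard ratio of 1.8 with
  182-subject tertile arms, a planted enriched set, 14/23 bound signature
  genes with 12/14 acetyl overlap, a known calibration line), so the whole
  pipeline is verifiable by parameter recovery without any external
  download.

I/O covers TSV/GCT 1.2 expression, GMT gene sets, BED6/narrowPeak
intervals (via rtracklayer/GenomicRanges), and clinical TSV tables, with
gzip handled transparently.

## Worked example

Derive a signature from a simulated tumor/normal study and test its
association with metastasis-free survival on a simulated cohort:

```r
library(PERKsig)

sim <- genExpressionStudy(seed = 1)   # 388 genes, 1093 tumors, 112 normals
sim$study
#> ExpressionStudy: 388 genes x 1205 samples
#>   groups: normal=112, tumor=1093

diff <- differentialExpression(sim$study)       # t-test per gene
sig  <- deriveSignature(diff)                   # twofold + Bonferroni
sig
#> GeneSignature with 23 genes
#>   members: gene0004, gene0043, gene0045, gene0089, gene0107, gene0120 ...
#>   provenance: fcThresholdLog2=1, alpha=0.05, nTests=388, bonferroniCutoff=0.000128866
setequal(geneIds(sig), sim$truth$plantedGenes)
#> [1] TRUE

coh    <- genSurvivalCohort(seed = 1)           # 547 subjects, true HR 1.8
tab    <- restrictFollowup(coh$table, 120)      # ten-year horizon
strata <- binByScore(coh$scores, "tertile")     # 182 vs 182 arms
logrankTest(tab, strata)
#> Two-group log-rank test
#>   high: observed 145, expected 103.664
#>   low: observed 99, expected 140.336
#>   chi-square = 29.0152 (1 df), p = 7.181e-08
hazardRatio(tab, strata)
#> Hazard ratio (mantel-haenszel): 1.983 [95% CI 1.538 - 2.556]
```

The derivation recovers exactly the 23 planted genes, and the top-tertile
arm shows the planted excess hazard: the estimate 1.98 is one cohort's
draw around the true 1.8 (the median across 200 cohorts is within ±0.15
of 1.8).

The remaining stages work the same way: `gsea()` on `genGseaStudy()`
output ranks the planted "EMT" set first; `annotatePeaks()` /
`bindingEnrichment()` / `colocalization()` on `genChipStudy()` output
reproduce 14/23 bound signature genes (binomial p < 0.01) and 86% (12/14)
H3K27ac co-localization; `fitCalibration()` / `estimateCtc()` invert
`genSpikein()` curves. `runPipeline()` chains everything from one YAML
config and writes a checksummed manifest.

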