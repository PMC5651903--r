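---
title: "Deriving and validating a cancer-specific pathway signature"
author: "PERKsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a cancer-specific pathway signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PERKsig)
```

## The analysis this package implements

PERK is an endoplasmic-reticulum stress kinase whose downstream
transcriptional program (via ATF4 and, in invasive breast tumors, the
transcription factor CREB3L1) promotes invasion and metastasis. PERKsig
implements, as reusable and tested components, the computational analysis
used to connect that pathway to clinical outcome:

1. **Signature derivation.** Starting from a pathway gene list (388 genes in
   the motivating study) measured in a tumor/normal expression cohort, each
   gene is tested by a two-sided, equal-variance Student *t*-test on
   `log2(x + 1)` values, with the fold change defined as the difference of
   group log-means. The *cancer-specific* subset is the genes at least
   twofold overexpressed (`log2fc >= 1`) that pass a Bonferroni-corrected
   0.05 threshold. On the motivating data this filter leaves a 23-gene
   signature (CSPS) whose only transcription factor is CREB3L1.
2. **Scoring and stratification.** A sample's signature score is the mean of
   `log2(x + 1)` over signature genes. Cohorts are stratified by ranking
   scores: top versus bottom tertile for survival contrasts, top half for
   defining pathway-high subsets, and a top/bottom 33-percentile scheme
   (optionally nested, pathway bin then EMT bin) for subgroup displays.
3. **Survival analysis.** Kaplan–Meier product-limit curves, the two-group
   log-rank test, and a Mantel–Haenszel hazard ratio
   `HR = (O1/E1)/(O2/E2)` with log-scale standard error
   `sqrt(1/E1 + 1/E2)`, after restricting follow-up to 120 months
   (metastasis over ten years).
4. **Enrichment.** Preranked GSEA over a gene-set collection: genes ranked
   by signal-to-noise `(m1 - m2)/(s1 + s2 + 1e-8)`, the weighted-KS
   enrichment score, a permutation null (phenotype permutations by
   default), NES normalization by the mean same-sign null ES, and the
   canonical pooled-NES FDR. A hypergeometric over-representation test
   covers GO-style queries.
5. **ChIP binding.** TF peaks are annotated to the closest TSS (summit
   anchor when present, else the interval center), signature genes bound by
   at least one peak are counted, and enrichment over the genome-wide
   background rate is assessed with an exact one-sided binomial tail.
   Co-localization with a second mark (H3K27ac) is direct, at-least-one-base
   overlap of the peak intervals.
6. **CTC calibration.** A luminescence standard curve over spiked cell
   counts (1000, 333, 111, 37, 12 cells in 0.4 ml blood) is fit by ordinary
   least squares of luminescence on count and inverted algebraically to turn
   readings into cells per ml.

The original cohorts (TCGA, GEO series, ENCODE ChIP) are not redistributed;
instead a synthetic-data module generates inputs with the same *printed*
design sizes and planted ground truth, so every stage is validated by
parameter recovery at desk scale.

## What the generators emulate — and what they do not

Each generator is a pure function of its arguments, including the seed.

**Expression (`genExpressionStudy`).** 388 genes x (1093 tumors + 112
normals). Per-gene baseline log2 levels are Uniform(3, 8); per-sample log2
values are Normal(baseline, 1); linear values are emitted as
`max(0, 2^z - 1)`, which makes `log2(x + 1)` the exact inverse for
non-negative `z`. Twenty-three randomly chosen genes receive a +2 log2
shift in tumors only. The Normal-on-log2 noise model was chosen because it
matches the *t*-test assumptions of the derivation stage; the motivating
study states no noise model, so recovery results say nothing about, e.g.,
count overdispersion or batch structure. No negative-binomial counts,
multi-cohort heterogeneity, or probe-collapsing artifacts are simulated.

**Survival (`genSurvivalCohort`).** 547 subjects — chosen so that the
compared tertile arms are exactly `floor(547/3) = 182`, making the printed
arm size a derived property rather than a coincidence. Scores are standard
normal; event times are exponential with rate 0.0076/month in the bottom
score tertile (a ~60% ten-year event fraction), `0.0076 * sqrt(1.8)` in the
middle and `0.0076 * 1.8` in the top tertile, so the true top-versus-bottom
hazard ratio is the printed 1.8. Follow-up is administratively censored at
120 months; no dropout process is simulated. Real metastasis cohorts are
heterogeneous multi-series data with non-exponential hazards; proportional
hazards with the printed HR is the minimal faithful structure.

**GSEA study (`genGseaStudy`).** 5000 genes, 50 sets of 100 (drawn with
replacement across sets, so sets may overlap — as hallmark collections do),
273 + 273 samples (halves of the 546 pathway-high tumors). The planted
"EMT" set gains +1 log2 in the high group. Because the planted effect is
strong and coherent, top-rank recovery is expected; the run does not probe
sensitivity at marginal effect sizes.

**ChIP (`genChipStudy`).** One 100-Mb chromosome with 20,000 TSSs on a 5-kb
grid with ±1.5-kb uniform jitter. The grid-plus-jitter layout (rather than
fully uniform placement) keeps neighboring TSSs at least 2 kb apart, which
guarantees that a peak planted within ±500 bp of a TSS is annotated back to
that gene — i.e. the planted truth (14 of 23 signature genes bound; H3K27ac
overlapping exactly 12 of those 14 peaks) is recoverable by construction.
The 20% background binding rate is an invented free parameter (the study
never states a genome-wide rate) and is exposed as an argument, as is the
86% background acetylation rate.

**Spike-in (`genSpikein`).** Luminescence `500 + 150 * count` times
lognormal noise (sdlog 0.05) at the five printed design counts.

## Numerical and design choices

* **Pseudocount 1** before every log2 transform; exposed everywhere as a
  parameter (the study says only "after adding a pseudocount").
* **Equal-variance Student t** is the default (the study names "Student's
  *t*-test"); Welch is available via `varEqual = FALSE`.
* **Fold change = difference of log-means**, not log of mean ratio,
  following the stated computation.
* **"Top half" of an odd cohort is `floor(N/2)`** — required for a 1093
  sample cohort to yield the printed 546 pathway-high tumors.
* **Ranking ties** (equal scores or metrics) break by ascending identifier,
  so stratification and GSEA rankings are bit-reproducible.
* **Log-rank/KM conventions:** subjects censored at an event time remain at
  risk for that event; zero-variance event times contribute nothing; a
  dataset with no events returns statistic 0, p = 1 with a warning.
* **Mantel–Haenszel rather than Cox** for the hazard ratio: the upstream
  web tool's estimator is unspecified, and the O/E ratio is closed-form,
  assumption-light, and matches Cox closely at these effect sizes (a
  univariate Cox fit is available with `method = "cox"`). This is a
  documented reproduction caveat.
* **GSEA:** signal-to-noise without desktop-style variance floors; weight
  1; set-size window [15, 500] after intersection with the measured genes;
  phenotype permutation by default with an automatic, warning-emitting
  switch to gene-set permutation below 7 samples per arm; `1e-8` guard on
  zero denominators. The enrichment score's sign resolves positive when the
  maximal positive and negative deviations tie within 1e-12, making the
  sign stable under floating-point accumulation order.
* **Degenerate inputs:** genes constant across both groups get t = 0,
  p = 1 and a flag; readings below the calibration intercept clamp to zero
  cells with a flag (blanks sit at or below the intercept); a derived
  background binding fraction of exactly 0 or 1 is an error with guidance
  rather than a silent Inf.
* **Peak anchoring:** summit when the narrowPeak summit offset is
  non-negative, else the interval center; closest-gene distance ignores
  strand (strand is cosmetic metadata). Distance ties resolve to the lower
  TSS coordinate. An optional `maxDistance` cap supports a window-based
  definition of "bound", since the upstream wording is ambiguous between
  windowed and pure closest-gene semantics; pure closest-gene is the
  default.
* **Calibration direction:** luminescence on count (classical calibration),
  inverted algebraically; a zero-intercept variant is available but not the
  default, since the upstream protocol does not state one.
* **Intervals** are held as `GRanges` (1-based, closed — the Bioconductor
  convention); BED/narrowPeak I/O performs the standard 0-based half-open
  conversion so file round-trips are exact and overlap semantics match the
  half-open definitions.

## Problem sizes used by the validation suite

The test suite runs the full printed design where it is cheap (388 x 1205
expression studies; 547-subject cohorts; the 5000 x 546 GSEA study with 200
permutations for 20 seeds; the 20,000-gene ChIP scenario) and scales down
where a property needs many replicates (e.g. 400 reduced ChIP scenarios for
binomial type-I control, 1000 null cohorts for log-rank type-I error, 60
reduced null studies for the Bonferroni false-positive bound). Scaled-down
scenarios change only the knobs documented above, never the planted-effect
structure. Cross-checks against independent implementations cover
Kaplan–Meier and the log-rank test (the survival package, equality within
1e-6 or better) and GSEA set ranking (fgsea, Spearman >= 0.9 on NES), and
every closed-form statistic (ES, binomial tail, hypergeometric p, closest
TSS, interval overlap) is compared with brute-force enumeration oracles on
small instances.

## What passing tests do and do not show

Recovery of the planted 23-gene signature, the 1.8 hazard ratio, the
top-ranked EMT set, the 14/23 binding enrichment and the 86%
co-localization demonstrates that the *pipeline computes its statistics
correctly* under data that satisfy its assumptions. It does not
re-establish the biological claims: real cohorts have unknown noise models,
confounding and heterogeneity that the generators deliberately do not
simulate, and the pathway gene list itself is consumed as an input, not
re-derived from the upstream knockout experiment.

## Known limitations

* No multivariable or stratified Cox models, competing risks, or interval
  censoring; no ssGSEA; no GO ontology structure (annotation is whatever
  GMT is supplied); no FDR alternative to Bonferroni in the derivation
  stage (the upstream filter is Bonferroni).
* Read alignment and peak calling are upstream of this package; peaks are
  consumed as BED6/narrowPeak files.
* The GCT reader/writer supports version 1.2 only.
* Microarray probe collapsing (used by the upstream survival web tool) is
  intentionally not replicated.

## End-to-end runs

`runPipeline()` executes all stages from one declarative (YAML or list)
config and writes a manifest with per-file MD5 checksums; identical configs
give identical checksums. Per-stage seeds are fixed offsets of the global
seed, so stages can be rerun in isolation without seed collisions. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.
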