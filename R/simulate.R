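## Synthetic-data generators. Each generator is a pure function of its
## arguments (seed included) and returns the generated objects together with
## a `truth` list recording the planted ground truth, so every downstream
## analysis stage can be verified by parameter recovery.

## log2-normal expression emitted on the linear scale. For log2 levels z
## with z >= 0 this is exactly invertible by log2(x + 1).
emit_linear <- function(z) pmax(2^z - 1, 0)

#' Simulate a tumor-versus-normal expression study with planted signature genes
#'
#' Emulates the design of a pathway-restricted tumor/normal comparison:
#' `nGenes` pathway genes measured in `nTumor` tumors and `nNormal`
#' normals. Per gene, a baseline log2 level is drawn from
#' `Uniform(baselineRange)`; per sample, a log2 value from
#' `Normal(baseline, sdLog2)`; linear values are emitted as
#' `max(0, 2^z - 1)`. A random subset of `nPlanted` genes receives an
#' additive `effectLog2` shift in tumor samples only — these are the genes
#' the signature-derivation stage should recover.
#'
#' @param nGenes,nTumor,nNormal design sizes (defaults mirror a 388-gene
#'   pathway over 1093 tumors and 112 normals).
#' @param nPlanted number of planted overexpressed genes (default 23).
#' @param effectLog2 planted tumor-only log2 shift (default 2, i.e. fourfold).
#' @param baselineRange range of per-gene baseline log2 levels.
#' @param sdLog2 per-sample log2 noise standard deviation.
#' @param seed integer seed; identical arguments give identical output.
#' @return A list with elements `study` ([ExpressionStudy] with groups
#'   `"tumor"`/`"normal"`) and `truth` (list with `plantedGenes`,
#'   `effectLog2`).
#' @export
genExpressionStudy <- function(nGenes = 388, nTumor = 1093, nNormal = 112,
                               nPlanted = 23, effectLog2 = 2,
                               baselineRange = c(3, 8), sdLog2 = 1,
                               seed = 1) {
  stopifnot(nGenes > 0, nTumor > 0, nNormal > 0)
  if (nPlanted > nGenes)
    stop("planted gene count (", nPlanted, ") exceeds gene count (", nGenes, ")")
  withr::with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(nGenes))
    samples <- c(sprintf("tumor%04d", seq_len(nTumor)),
                 sprintf("normal%03d", seq_len(nNormal)))
    group <- rep(c("tumor", "normal"), c(nTumor, nNormal))
    mu <- runif(nGenes, baselineRange[1], baselineRange[2])
    z <- matrix(rnorm(nGenes * length(samples), mean = mu, sd = sdLog2),
                nrow = nGenes, dimnames = list(genes, samples))
    planted <- sort(sample(genes, nPlanted))
    z[planted, group == "tumor"] <- z[planted, group == "tumor"] + effectLog2
    study <- ExpressionStudy(emit_linear(z), group = group)
    list(study = study,
         truth = list(plantedGenes = planted, effectLog2 = effectLog2))
  })
}

#' Simulate a survival cohort with score-dependent proportional hazards
#'
#' Subjects receive a standard-normal signature score and are ranked into
#' score tertiles (same deterministic rule as [binByScore()]). Event times
#' are exponential with rate `baseRate` in the bottom tertile,
#' `baseRate * sqrt(hazardRatio)` in the middle and
#' `baseRate * hazardRatio` in the top tertile; follow-up is
#' administratively censored at `horizonMonths`. The default cohort size of
#' 547 makes each compared tertile arm exactly `floor(547/3) = 182`.
#'
#' @param nSubjects cohort size (default 547).
#' @param baseRate bottom-tertile event rate per month (default 0.0076,
#'   i.e. ~60% ten-year event fraction).
#' @param hazardRatio true top-versus-bottom hazard ratio (default 1.8).
#' @param horizonMonths administrative censoring horizon (default 120).
#' @param seed integer seed.
#' @return A list with `table` (survival `data.frame`: `sample`, `time`,
#'   `event`), `scores` (named numeric vector), and `truth` (list with
#'   `hazardRatio`, `rates`, `strata`).
#' @export
genSurvivalCohort <- function(nSubjects = 547, baseRate = 0.0076,
                              hazardRatio = 1.8, horizonMonths = 120,
                              seed = 1) {
  stopifnot(nSubjects >= 3, horizonMonths > 0)
  if (baseRate <= 0 || hazardRatio <= 0)
    stop("event rates must be positive")
  withr::with_seed(seed, {
    ids <- sprintf("subj%04d", seq_len(nSubjects))
    score <- setNames(rnorm(nSubjects), ids)
    strata <- binByScore(score, scheme = "tertile")
    rate <- setNames(rep(baseRate * sqrt(hazardRatio), nSubjects), ids)
    rate[strata$sample[strata$stratum == "low"]] <- baseRate
    rate[strata$sample[strata$stratum == "high"]] <- baseRate * hazardRatio
    t_event <- rexp(nSubjects, rate = rate)
    tab <- data.frame(sample = ids,
                      time = pmin(t_event, horizonMonths),
                      event = as.integer(t_event <= horizonMonths),
                      stringsAsFactors = FALSE)
    list(table = tab, scores = score,
         truth = list(hazardRatio = hazardRatio,
                      rates = c(low = baseRate,
                                mid = baseRate * sqrt(hazardRatio),
                                high = baseRate * hazardRatio),
                      strata = strata))
  })
}

#' Simulate a two-group expression study with one planted enriched gene set
#'
#' Emulates the design of a hallmark-collection GSEA comparing two halves of
#' a cohort: `nGenes` genes, `nSets` random sets of `setSize` members (one
#' named `plantedSetName`), and `nHigh` + `nLow` samples. Genes of the
#' planted set receive a `shiftLog2` mean shift in the high group; values
#' are emitted linear as in [genExpressionStudy()].
#'
#' @param nGenes gene universe size (default 5000).
#' @param nSets,setSize gene-set collection design (default 50 sets of 100).
#' @param nHigh,nLow group sizes (default 273 each, halves of 546).
#' @param shiftLog2 planted log2 shift in the high group (default 1).
#' @param plantedSetName name of the planted set (default `"EMT"`).
#' @param baselineRange,sdLog2 as in [genExpressionStudy()].
#' @param seed integer seed.
#' @return A list with `study` ([ExpressionStudy] with groups
#'   `"high"`/`"low"`), `collection` (named list of gene sets) and `truth`
#'   (list with `plantedSet`, `shiftLog2`).
#' @export
genGseaStudy <- function(nGenes = 5000, nSets = 50, setSize = 100,
                         nHigh = 273, nLow = 273, shiftLog2 = 1,
                         plantedSetName = "EMT", baselineRange = c(3, 8),
                         sdLog2 = 1, seed = 1) {
  if (setSize > nGenes)
    stop("set size (", setSize, ") exceeds gene universe (", nGenes, ")")
  withr::with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(nGenes))
    samples <- c(sprintf("high%04d", seq_len(nHigh)),
                 sprintf("low%04d", seq_len(nLow)))
    group <- rep(c("high", "low"), c(nHigh, nLow))
    collection <- lapply(seq_len(nSets), function(i) sort(sample(genes, setSize)))
    names(collection) <- c(plantedSetName,
                           sprintf("SET%02d", seq_len(nSets - 1)))
    mu <- runif(nGenes, baselineRange[1], baselineRange[2])
    z <- matrix(rnorm(nGenes * length(samples), mean = mu, sd = sdLog2),
                nrow = nGenes, dimnames = list(genes, samples))
    planted <- collection[[plantedSetName]]
    z[planted, group == "high"] <- z[planted, group == "high"] + shiftLog2
    study <- ExpressionStudy(emit_linear(z), group = group)
    list(study = study, collection = collection,
         truth = list(plantedSet = plantedSetName, shiftLog2 = shiftLog2))
  })
}

narrowpeak_granges <- function(chrom, start0, end0, name, summit_offset,
                               chrom_length) {
  clip_lo <- start0 < 0
  clip_hi <- end0 > chrom_length
  if (any(clip_lo | clip_hi)) {
    warning(sum(clip_lo | clip_hi),
            " peak(s) extended beyond the chromosome and were clipped",
            call. = FALSE)
    start0 <- pmax(start0, 0)
    end0 <- pmin(end0, chrom_length)
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0))
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$score <- 0L
  S4Vectors::mcols(gr)$signalValue <- round(runif(length(gr), 5, 50), 3)
  S4Vectors::mcols(gr)$pValue <- -1
  S4Vectors::mcols(gr)$qValue <- -1
  S4Vectors::mcols(gr)$peak <- as.integer(summit_offset)
  gr
}

#' Simulate TF and histone-mark peak sets around a synthetic gene annotation
#'
#' One synthetic chromosome carries `nGenes` TSSs laid out on a regular grid
#' with uniform jitter (so neighboring TSSs never approach closer than the
#' peak placement window, keeping closest-gene assignment of planted peaks
#' unambiguous). Of `nSignature` designated signature genes,
#' `nBoundSignature` receive a TF peak whose summit falls within
#' `maxOffset` bp of the TSS; a `backgroundRate` fraction of the remaining
#' genes is bound the same way. H3K27ac-like peaks are placed to directly
#' overlap the TF peak at exactly `nAcetylSignature` of the bound signature
#' genes and at a `backgroundAcetylRate` fraction of bound background genes.
#'
#' @param chromLength chromosome length in bp (default 100 Mb).
#' @param nGenes number of genes (default 20000).
#' @param nSignature designated signature genes (default 23).
#' @param nBoundSignature signature genes given a TF peak (default 14).
#' @param nAcetylSignature bound signature genes whose TF peak overlaps an
#'   acetyl peak (default 12).
#' @param backgroundRate binding probability for non-signature genes
#'   (default 0.2).
#' @param backgroundAcetylRate acetyl-overlap probability for bound
#'   background genes (default 0.86).
#' @param peakWidth TF peak width in bp (default 400).
#' @param maxOffset maximum |summit - TSS| distance in bp (default 500).
#' @param acetylWidth acetyl peak width in bp (default 1000).
#' @param seed integer seed.
#' @return A list with `tfPeaks` and `acetylPeaks` (`GRanges` with
#'   narrowPeak metadata), `loci` (gene-locus `data.frame`),
#'   `signatureGenes` (character) and `truth` (list with
#'   `boundSignatureGenes`, `acetylOverlapCount`, `backgroundBoundFraction`).
#' @export
genChipStudy <- function(chromLength = 1e8, nGenes = 20000, nSignature = 23,
                         nBoundSignature = 14, nAcetylSignature = 12,
                         backgroundRate = 0.2, backgroundAcetylRate = 0.86,
                         peakWidth = 400, maxOffset = 500,
                         acetylWidth = 1000, seed = 1) {
  stopifnot(nSignature <= nGenes, nBoundSignature <= nSignature,
            nAcetylSignature <= nBoundSignature,
            backgroundRate > 0, backgroundRate < 1)
  withr::with_seed(seed, {
    spacing <- floor(chromLength / nGenes)
    jitter_max <- max(0, floor((spacing - 2 * (maxOffset + peakWidth)) / 2))
    genes <- sprintf("gene%05d", seq_len(nGenes))
    tss <- (seq_len(nGenes) - 1) * spacing + floor(spacing / 2) +
      round(runif(nGenes, -jitter_max, jitter_max))
    loci <- data.frame(gene = genes, chrom = "chrS", tss = tss,
                       strand = sample(c("+", "-"), nGenes, replace = TRUE),
                       stringsAsFactors = FALSE)
    signature <- sort(sample(genes, nSignature))
    bound_sig <- sort(sample(signature, nBoundSignature))
    background <- setdiff(genes, signature)
    bound_bg <- background[runif(length(background)) < backgroundRate]
    bound <- c(bound_sig, bound_bg)
    centers <- tss[match(bound, genes)] +
      round(runif(length(bound), -maxOffset, maxOffset))
    half <- floor(peakWidth / 2)
    tf <- narrowpeak_granges("chrS", centers - half, centers - half + peakWidth,
                             paste0("tf_", bound), half, chromLength)
    acetyl_sig <- sort(sample(bound_sig, nAcetylSignature))
    acetyl_bg <- bound_bg[runif(length(bound_bg)) < backgroundAcetylRate]
    acetyl_genes <- c(acetyl_sig, acetyl_bg)
    ac_centers <- centers[match(acetyl_genes, bound)]
    ac_half <- floor(acetylWidth / 2)
    acetyl <- narrowpeak_granges("chrS", ac_centers - ac_half,
                                 ac_centers - ac_half + acetylWidth,
                                 paste0("ac_", acetyl_genes), ac_half,
                                 chromLength)
    list(tfPeaks = tf, acetylPeaks = acetyl, loci = loci,
         signatureGenes = signature,
         truth = list(boundSignatureGenes = bound_sig,
                      acetylOverlapCount = nAcetylSignature,
                      backgroundBoundFraction = length(bound_bg) / length(background)))
  })
}

#' Simulate a spike-in luminescence standard-curve series
#'
#' Luminescence at each spiked cell count is `intercept + slope * count`,
#' multiplied by lognormal noise with log-scale standard deviation
#' `sigmaLog`. The default design points are the spiked cell numbers of the
#' circulating-tumor-cell calibration protocol.
#'
#' @param counts spiked cell counts (default `c(1000, 333, 111, 37, 12)`).
#' @param intercept,slope true line (defaults 500 and 150).
#' @param sigmaLog lognormal noise sd on the log scale (default 0.05);
#'   `0` gives exactly collinear points.
#' @param seed integer seed.
#' @return A list with `counts`, `luminescence` and `truth` (list with
#'   `intercept`, `slope`).
#' @export
genSpikein <- function(counts = c(1000, 333, 111, 37, 12), intercept = 500,
                       slope = 150, sigmaLog = 0.05, seed = 1) {
  if (slope <= 0) stop("slope must be positive")
  withr::with_seed(seed, {
    lum <- (intercept + slope * counts) *
      rlnorm(length(counts), meanlog = 0, sdlog = sigmaLog)
    list(counts = counts, luminescence = lum,
         truth = list(intercept = intercept, slope = slope))
  })
}

#' Generate one named scenario and write its files
#'
#' Runs the generator behind a scenario id and writes its outputs in the
#' package's standard formats plus a `truth.json` sidecar:
#' * `S-CSPS` — tumor/normal expression study ([genExpressionStudy()]);
#'   writes `expression.tsv`, `samples.tsv`.
#' * `M1` — survival cohort ([genSurvivalCohort()]); writes
#'   `survival.tsv`, `scores.tsv`.
#' * `G1` — two-group study with a planted set ([genGseaStudy()]); writes
#'   `expression.tsv`, `samples.tsv`, `sets.gmt`.
#' * `C1` — TF + acetyl peak sets with a gene annotation
#'   ([genChipStudy()]); writes `tf.narrowPeak`, `acetyl.narrowPeak`,
#'   `loci.tsv`, `signature.gmt`.
#' * `SPIKE` — spike-in series ([genSpikein()]); writes `spikein.tsv`.
#'
#' @param scenario one of `"S-CSPS"`, `"M1"`, `"G1"`, `"C1"`, `"SPIKE"`.
#' @param seed integer seed.
#' @param outDir output directory (created if needed).
#' @param overrides named list of generator arguments to override.
#' @return The generator's return value, invisibly, with an extra `files`
#'   element listing the written paths.
#' @export
simulateScenario <- function(scenario = c("S-CSPS", "M1", "G1", "C1", "SPIKE"),
                             seed = 1, outDir, overrides = list()) {
  scenario <- match.arg(scenario)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  call_gen <- function(fun, extra = list())
    do.call(fun, modifyList(c(list(seed = seed), extra), overrides))
  res <- switch(scenario,
    "S-CSPS" = {
      r <- call_gen(genExpressionStudy)
      writeExpression(r$study, p("expression.tsv"))
      write_groups(r$study, p("samples.tsv"))
      r$files <- p(c("expression.tsv", "samples.tsv"))
      r
    },
    "M1" = {
      r <- call_gen(genSurvivalCohort)
      writeSurvival(r$table, p("survival.tsv"))
      writeScores(r$scores, p("scores.tsv"))
      r$files <- p(c("survival.tsv", "scores.tsv"))
      r
    },
    "G1" = {
      r <- call_gen(genGseaStudy)
      writeExpression(r$study, p("expression.tsv"))
      write_groups(r$study, p("samples.tsv"))
      writeGmt(r$collection, p("sets.gmt"))
      r$files <- p(c("expression.tsv", "samples.tsv", "sets.gmt"))
      r
    },
    "C1" = {
      r <- call_gen(genChipStudy)
      writeIntervals(r$tfPeaks, p("tf.narrowPeak"), format = "narrowPeak")
      writeIntervals(r$acetylPeaks, p("acetyl.narrowPeak"),
                     format = "narrowPeak")
      writeLoci(r$loci, p("loci.tsv"))
      writeGmt(list(signature = r$signatureGenes), p("signature.gmt"))
      r$files <- p(c("tf.narrowPeak", "acetyl.narrowPeak", "loci.tsv",
                     "signature.gmt"))
      r
    },
    "SPIKE" = {
      r <- call_gen(genSpikein)
      con <- out_con(p("spikein.tsv"))
      utils::write.table(data.frame(count = r$counts,
                                    luminescence = r$luminescence),
                         con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      r$files <- p("spikein.tsv")
      r
    })
  jsonlite::write_json(res$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  res$files <- c(res$files, p("truth.json"))
  invisible(res)
}

write_groups <- function(study, path) {
  g <- sampleGroup(study)
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(data.frame(sample = names(g), group = unname(g)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
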