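## End-to-end orchestration: simulate (or read) every input, derive the
## signature, stratify, run survival / GSEA / ChIP / CTC stages, and write a
## run manifest with input checksums so a run is reproducible bit-for-bit.

default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "signature", "survival", "gsea", "chip", "ctc"),
    inputs = list(),
    scenarios = list(),
    signature = list(fc_threshold_log2 = 1, alpha = 0.05, pseudocount = 1,
                     tumor_label = "tumor", normal_label = "normal"),
    survival = list(horizon_months = 120, scheme = "tertile"),
    gsea = list(n_perm = 1000, weight = 1, min_size = 15, max_size = 500,
                perm_type = "phenotype"),
    chip = list(max_distance = NULL),
    ctc = list(sample_volume_ml = 0.4, zero_intercept = FALSE)
  )
}

known_config_keys <- function() names(default_config())

## per-stage deterministic seed substreams derived from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(`S-CSPS` = 0L, M1 = 1L, G1 = 2L, C1 = 3L, SPIKE = 4L,
               gsea = 10L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- modifyList(base, config)
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config field 'seed' must be a single integer")
  bad <- setdiff(config$stages, base$stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  ## when simulation is off, every enabled stage must name its inputs
  if (!"simulate" %in% config$stages) {
    need <- list(
      signature = c("expression", "samples"),
      survival = c("survival", "scores"),
      gsea = c("gsea_expression", "gsea_samples", "gene_sets"),
      chip = c("tf_peaks", "acetyl_peaks", "loci", "chip_signature"),
      ctc = c("spikein"))
    for (st in intersect(config$stages, names(need))) {
      missing <- setdiff(need[[st]], names(config$inputs))
      if (length(missing))
        stop("stage '", st, "' enabled without simulation but config ",
             "inputs are missing field(s): ", paste(missing, collapse = ", "))
    }
  }
  config
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> derive signature -> score/stratify -> survival
#' -> GSEA -> ChIP enrichment -> CTC calibration from one declarative
#' config, writing every stage's outputs in the package's standard formats
#' plus a `manifest.json` recording the resolved config, package version
#' and MD5 checksum of every written file. With the `simulate` stage
#' enabled (the default), all inputs are generated by the scenario
#' generators under deterministic per-stage seed substreams of the global
#' seed; otherwise the `inputs` config section must name each file.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   All fields are optional when simulation is on; see the package
#'   vignette for the schema. Unknown fields and missing required inputs
#'   are schema errors naming the field.
#' @param outDir run directory (created; existing files are overwritten).
#' @return The manifest, invisibly (a list with `config`, `version`,
#'   `checksums`).
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(path) written <<- c(written, path)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  sim_dir <- function(scn) file.path(outDir, "simulate", scn)
  inp <- function(field, scn, file) {
    if (!is.null(config$inputs[[field]])) return(config$inputs[[field]])
    path <- file.path(sim_dir(scn), file)
    if (!file.exists(path))
      stop("input '", field, "' not configured and scenario ", scn,
           " was not simulated")
    path
  }

  if ("simulate" %in% config$stages) run_stage("simulate", {
    for (scn in c("S-CSPS", "M1", "G1", "C1", "SPIKE")) {
      r <- simulateScenario(scn, seed = stage_seed(config$seed, scn),
                            outDir = sim_dir(scn),
                            overrides = config$scenarios[[scn]] %||% list())
      for (f in r$files) emit(f)
    }
  })

  if ("signature" %in% config$stages) run_stage("signature", {
    sg <- config$signature
    study <- readExpression(inp("expression", "S-CSPS", "expression.tsv"),
                            annotation = inp("samples", "S-CSPS", "samples.tsv"))
    diff <- differentialExpression(study, tumorLabel = sg$tumor_label,
                                   normalLabel = sg$normal_label,
                                   pseudocount = sg$pseudocount)
    sig <- deriveSignature(diff, fcThresholdLog2 = sg$fc_threshold_log2,
                           alpha = sg$alpha)
    d <- file.path(outDir, "signature")
    dir.create(d, showWarnings = FALSE)
    con <- out_con(file.path(d, "differential.tsv"))
    utils::write.table(diff, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    emit(file.path(d, "differential.tsv"))
    writeGmt(list(signature = geneIds(sig)), file.path(d, "signature.gmt"))
    emit(file.path(d, "signature.gmt"))
    scores <- scoreSamples(study, sig, pseudocount = sg$pseudocount)
    writeScores(scores, file.path(d, "scores.tsv"))
    emit(file.path(d, "scores.tsv"))
    for (scheme in c("tertile", "half")) {
      strata <- binByScore(scores, scheme = scheme)
      writeStrata(strata, file.path(d, paste0("strata_", scheme, ".tsv")))
      emit(file.path(d, paste0("strata_", scheme, ".tsv")))
    }
  })

  if ("survival" %in% config$stages) run_stage("survival", {
    sv <- config$survival
    tab <- restrictFollowup(readSurvival(inp("survival", "M1", "survival.tsv")),
                            horizonMonths = sv$horizon_months)
    scores <- readScores(inp("scores", "M1", "scores.tsv"))
    strata <- binByScore(scores, scheme = sv$scheme)
    d <- file.path(outDir, "survival")
    dir.create(d, showWarnings = FALSE)
    for (g in c("high", "low")) {
      km <- kmEstimate(tab[tab$sample %in% strata$sample[
        !is.na(strata$stratum) & strata$stratum == g], , drop = FALSE])
      con <- out_con(file.path(d, paste0("km_", g, ".tsv")))
      utils::write.table(km, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      emit(file.path(d, paste0("km_", g, ".tsv")))
    }
    lr <- logrankTest(tab, strata)
    hr <- hazardRatio(tab, strata)
    jsonlite::write_json(
      list(observed = as.list(lr@observed), expected = as.list(lr@expected),
           statistic = lr@statistic, p.value = lr@p.value, hr = hr@hr,
           hr_conf_low = hr@conf.low, hr_conf_high = hr@conf.high),
      file.path(d, "survival_summary.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(d, "survival_summary.json"))
  })

  if ("gsea" %in% config$stages) run_stage("gsea", {
    gc <- config$gsea
    study <- readExpression(inp("gsea_expression", "G1", "expression.tsv"),
                            annotation = inp("gsea_samples", "G1", "samples.tsv"))
    sets <- readGmt(inp("gene_sets", "G1", "sets.gmt"))
    res <- gsea(study, collection = sets, nPerm = gc$n_perm,
                seed = stage_seed(config$seed, "gsea"),
                permType = gc$perm_type, weight = gc$weight,
                minSize = gc$min_size, maxSize = gc$max_size)
    d <- file.path(outDir, "gsea")
    dir.create(d, showWarnings = FALSE)
    con <- out_con(file.path(d, "gsea.tsv"))
    utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    emit(file.path(d, "gsea.tsv"))
  })

  if ("chip" %in% config$stages) run_stage("chip", {
    tf <- readIntervals(inp("tf_peaks", "C1", "tf.narrowPeak"), "narrowPeak")
    acetyl <- readIntervals(inp("acetyl_peaks", "C1", "acetyl.narrowPeak"),
                            "narrowPeak")
    loci <- readLoci(inp("loci", "C1", "loci.tsv"))
    sig <- readGmt(inp("chip_signature", "C1", "signature.gmt"))[[1]]
    ann <- annotatePeaks(tf, loci)
    bound <- boundGenes(ann, maxDistance = config$chip$max_distance)
    be <- bindingEnrichment(sig, bound, loci)
    sig_peaks <- tf[!is.na(ann$gene) & ann$gene %in% sig]
    ov <- colocalization(sig_peaks, acetyl)
    d <- file.path(outDir, "chip")
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(
      list(k = be@k, n = be@n, p0 = be@p0, p.value = be@p.value,
           colocalization_fraction = ov@fraction,
           colocalization_overlapping = ov@overlapping,
           colocalization_considered = ov@considered),
      file.path(d, "chip_summary.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(d, "chip_summary.json"))
  })

  if ("ctc" %in% config$stages) run_stage("ctc", {
    sp <- utils::read.delim(inp("spikein", "SPIKE", "spikein.tsv"))
    fit <- fitCalibration(sp$count, sp$luminescence,
                          zeroIntercept = config$ctc$zero_intercept)
    est <- estimateCtc(sp$luminescence, fit,
                       sampleVolumeMl = config$ctc$sample_volume_ml)
    d <- file.path(outDir, "ctc")
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(
      list(slope = fit@slope, intercept = fit@intercept,
           r.squared = fit@r.squared, sigma = fit@sigma),
      file.path(d, "calibration.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(d, "calibration.json"))
    con <- out_con(file.path(d, "estimates.tsv"))
    utils::write.table(est, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    emit(file.path(d, "estimates.tsv"))
  })

  files <- sort(unique(written))
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", normalizePath(outDir), "/?"), "",
                          normalizePath(files))
  manifest <- list(
    config = config,
    version = as.character(utils::packageVersion("PERKsig")),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
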