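#' ExpressionStudy: a linear-scale expression matrix with sample groups
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay `"exprs"`: a gene x sample matrix of non-negative, finite,
#' linear-scale expression values. An optional `group` column in `colData`
#' carries per-sample labels (e.g. `"tumor"` / `"normal"`); grouped
#' operations require it. All log transforms happen inside the analysis
#' functions, never at I/O time.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); linear scale, `>= 0`.
#' @param group optional character vector of per-sample group labels,
#'   parallel to `colnames(values)`.
#' @return An `ExpressionStudy` object.
#' @examples
#' m <- matrix(c(3, 7, 15, 1, 3, 9), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' es <- ExpressionStudy(m, group = c("tumor", "tumor", "normal"))
#' sampleGroup(es)
#' @export
ExpressionStudy <- function(values, group = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(group)) {
    if (length(group) != ncol(values))
      stop("'group' must have one label per sample (", ncol(values), ")")
    cd$group <- as.character(group)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("ExpressionStudy", se)
}

#' @rdname ExpressionStudy
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is missing")
  x <- SummarizedExperiment::assay(object, "exprs")
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    msg <- c(msg, paste0("duplicate gene ids: ",
                         paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    msg <- c(msg, paste0("duplicate sample ids: ",
                         paste(head(dup, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    msg <- c(msg, paste0("non-finite or negative expression at gene '",
                         rownames(x)[bad[1, 1]], "', sample '",
                         colnames(x)[bad[1, 2]], "'",
                         if (nrow(bad) > 1)
                           paste0(" (and ", nrow(bad) - 1, " more cells)")))
  }
  if (length(msg)) msg else TRUE
})

#' GeneSignature: a derived gene list with its provenance
#'
#' Holds the member gene ids of a derived signature together with the
#' thresholds that produced it (fold-change cutoff, alpha, number of tests,
#' pseudocount), so a signature is never separated from its derivation.
#'
#' @param members character vector of member gene ids (deduplicated).
#' @param provenance named list recording how the signature was derived.
#' @return A `GeneSignature` object.
#' @seealso [deriveSignature()]
#' @export
GeneSignature <- function(members, provenance = list()) {
  new("GeneSignature", members = unique(as.character(members)),
      provenance = provenance)
}

#' @rdname GeneSignature
#' @export
setClass("GeneSignature",
         representation(members = "character", provenance = "list"))

setValidity("GeneSignature", function(object) {
  if (anyDuplicated(object@members)) "duplicate member gene ids" else TRUE
})

#' Two-group log-rank test result
#'
#' Observed and expected event counts per group, the hypergeometric variance
#' of the observed-minus-expected accumulator, the 1-df chi-square statistic
#' and its two-sided p-value.
#'
#' @slot observed named numeric, observed events per group.
#' @slot expected named numeric, expected events per group.
#' @slot variance numeric, variance of O - E.
#' @slot statistic numeric, chi-square statistic (1 df).
#' @slot p.value numeric, two-sided p-value.
#' @export
setClass("LogRankResult",
         representation(observed = "numeric", expected = "numeric",
                        variance = "numeric", statistic = "numeric",
                        p.value = "numeric"))

#' Mantel-Haenszel hazard ratio estimate
#'
#' @slot hr numeric, (O1/E1)/(O2/E2).
#' @slot se.log numeric, log-scale standard error sqrt(1/E1 + 1/E2).
#' @slot conf.low,conf.high numeric, 95% confidence limits.
#' @slot method character, "mantel-haenszel" or "cox".
#' @export
setClass("HazardRatioEstimate",
         representation(hr = "numeric", se.log = "numeric",
                        conf.low = "numeric", conf.high = "numeric",
                        method = "character"))

#' Binomial binding-enrichment result
#'
#' @slot k integer, bound signature genes.
#' @slot n integer, signature size.
#' @slot p0 numeric, background bound fraction.
#' @slot p.value numeric, one-sided binomial tail P(X >= k).
#' @export
setClass("BindingEnrichment",
         representation(k = "integer", n = "integer", p0 = "numeric",
                        p.value = "numeric"))

#' Peak co-localization summary
#'
#' @slot considered integer, peaks considered.
#' @slot overlapping integer, peaks sharing >= 1 base with the second mark.
#' @slot fraction numeric, overlapping / considered.
#' @export
setClass("OverlapSummary",
         representation(considered = "integer", overlapping = "integer",
                        fraction = "numeric"))

#' Spike-in calibration fit
#'
#' Ordinary least squares of luminescence on spiked cell count (classical
#' calibration direction); inverted by [estimateCtc()].
#'
#' @slot slope numeric, radiance per cell.
#' @slot intercept numeric, radiance at zero cells.
#' @slot r.squared numeric, coefficient of determination.
#' @slot sigma numeric, residual standard deviation.
#' @slot counts numeric, design points used.
#' @export
setClass("CalibrationFit",
         representation(slope = "numeric", intercept = "numeric",
                        r.squared = "numeric", sigma = "numeric",
                        counts = "numeric"))

setValidity("CalibrationFit", function(object) {
  if (length(object@r.squared) == 1 &&
      (object@r.squared < -1e-8 || object@r.squared > 1 + 1e-8))
    "r.squared outside [0, 1]" else TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  g <- sampleGroup(object)
  if (!is.null(g)) {
    tab <- table(g)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  groups: <none>\n")
})

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature with", length(object@members), "genes\n")
  cat("  members:", paste(head(object@members, 6), collapse = ", "),
      if (length(object@members) > 6) "...\n" else "\n")
  if (length(object@provenance))
    cat("  provenance:",
        paste(names(object@provenance),
              vapply(object@provenance, function(v)
                paste(format(v), collapse = ","), character(1)),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LogRankResult", function(object) {
  cat("Two-group log-rank test\n")
  for (g in names(object@observed))
    cat(sprintf("  %s: observed %g, expected %.3f\n",
                g, object@observed[[g]], object@expected[[g]]))
  cat(sprintf("  chi-square = %.4f (1 df), p = %.4g\n",
              object@statistic, object@p.value))
})

setMethod("show", "HazardRatioEstimate", function(object) {
  cat(sprintf("Hazard ratio (%s): %.3f [95%% CI %.3f - %.3f]\n",
              object@method, object@hr, object@conf.low, object@conf.high))
})

setMethod("show", "BindingEnrichment", function(object) {
  cat(sprintf("Binding enrichment: %d/%d signature genes bound (background p0 = %.3f)\n",
              object@k, object@n, object@p0))
  cat(sprintf("  one-sided binomial p = %.3g\n", object@p.value))
})

setMethod("show", "OverlapSummary", function(object) {
  cat(sprintf("Overlap: %d/%d peaks (%.1f%%) co-localized\n",
              object@overlapping, object@considered, 100 * object@fraction))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("Calibration fit: luminescence = %.4g + %.4g x cells (r2 = %.4f)\n",
              object@intercept, object@slope, object@r.squared))
})
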