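#' Accessors for PERKsig objects
#'
#' `exprValues` returns the linear-scale expression matrix, `sampleGroup`
#' the per-sample group labels (or `NULL`), `geneIds` the gene identifiers
#' and `sampleIds` the sample identifiers of an [ExpressionStudy];
#' `geneIds` on a [GeneSignature] returns the member genes and
#' `provenance` the thresholds that derived it.
#'
#' @param x an `ExpressionStudy` or `GeneSignature`.
#' @return A matrix, character vector, list, or `NULL` (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionStudy", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' @rdname accessors
#' @export
setMethod("sampleGroup", "ExpressionStudy", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) setNames(cd$group, rownames(cd)) else NULL
})

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionStudy", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSignature", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionStudy", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("provenance", "GeneSignature", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("length", "GeneSignature", function(x) length(x@members))
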