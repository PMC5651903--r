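## Signature derivation: tumor-vs-normal differential expression on
## log2(x + pseudocount) values, a fold-change + Bonferroni filter, mean
## signature scoring and rank-based stratification.

log2p <- function(x, pseudocount = 1) log2(x + pseudocount)

row_means_vars <- function(x) {
  m <- rowMeans(x)
  n <- ncol(x)
  v <- if (n > 1) rowSums((x - m)^2) / (n - 1) else rep(NA_real_, nrow(x))
  list(mean = m, var = v, n = n)
}

#' Per-gene tumor-versus-normal differential expression
#'
#' For each gene, computes the difference of group means of
#' `log2(x + pseudocount)` (tumor minus normal) and a two-sided two-sample
#' Student t-test (equal-variance by default, Welch behind `varEqual =
#' FALSE`). Genes constant across all samples of both groups get `t = 0`,
#' `p = 1` and are flagged.
#'
#' @param study an [ExpressionStudy] with group labels.
#' @param tumorLabel,normalLabel group labels to compare
#'   (defaults `"tumor"`, `"normal"`).
#' @param pseudocount added before the log2 transform (default 1).
#' @param varEqual pooled-variance Student t (default) or Welch.
#' @return A `data.frame` with one row per gene: `gene`, `meanTumor`,
#'   `meanNormal`, `log2fc`, `t`, `df`, `p`, `constant`.
#' @examples
#' m <- rbind(g1 = c(3, 7, 15, 1, 3))
#' colnames(m) <- paste0("s", 1:5)
#' es <- ExpressionStudy(m, group = c(rep("tumor", 3), rep("normal", 2)))
#' differentialExpression(es)  # log2fc 1.5, t 1.8 on 3 df
#' @export
differentialExpression <- function(study, tumorLabel = "tumor",
                                   normalLabel = "normal", pseudocount = 1,
                                   varEqual = TRUE) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  g <- sampleGroup(study)
  if (is.null(g)) stop("study has no sample group labels")
  x <- log2p(exprValues(study), pseudocount)
  xt <- x[, g == tumorLabel, drop = FALSE]
  xn <- x[, g == normalLabel, drop = FALSE]
  if (ncol(xt) < 2 || ncol(xn) < 2)
    stop("need >= 2 samples per group (got ", ncol(xt), " '", tumorLabel,
         "', ", ncol(xn), " '", normalLabel, "')")
  st <- row_means_vars(xt)
  sn <- row_means_vars(xn)
  n1 <- st$n; n2 <- sn$n
  log2fc <- st$mean - sn$mean
  if (varEqual) {
    sp2 <- ((n1 - 1) * st$var + (n2 - 1) * sn$var) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    a <- st$var / n1; b <- sn$var / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tval <- log2fc / se
  p <- 2 * pt(-abs(tval), df)
  constant <- se == 0 & log2fc == 0
  ## a gene flat within groups but different between them is infinitely
  ## significant; a gene flat everywhere carries no evidence
  tval[se == 0] <- ifelse(log2fc[se == 0] == 0, 0, sign(log2fc[se == 0]) * Inf)
  p[se == 0] <- ifelse(log2fc[se == 0] == 0, 1, 0)
  data.frame(gene = rownames(x), meanTumor = unname(st$mean),
             meanNormal = unname(sn$mean), log2fc = unname(log2fc),
             t = unname(tval), df = unname(df), p = unname(p),
             constant = unname(constant), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Derive a cancer-specific signature from a differential table
#'
#' Members are the genes at least `fcThresholdLog2` log2-fold overexpressed
#' (difference of log means) whose two-sided p-value passes the
#' Bonferroni-corrected threshold `alpha / nTests`. The thresholds are
#' recorded in the signature's provenance.
#'
#' @param diff a differential table from [differentialExpression()].
#' @param fcThresholdLog2 minimum log2 fold change (default 1, i.e. twofold).
#' @param alpha family-wise significance level before correction
#'   (default 0.05).
#' @param nTests number of tests for the Bonferroni correction (defaults to
#'   the number of genes tested).
#' @return A [GeneSignature].
#' @export
deriveSignature <- function(diff, fcThresholdLog2 = 1, alpha = 0.05,
                            nTests = nrow(diff)) {
  if (nrow(diff) == 0) {
    warning("empty differential table; returning empty signature")
    return(GeneSignature(character(),
                         provenance = list(fcThresholdLog2 = fcThresholdLog2,
                                           alpha = alpha, nTests = 0)))
  }
  if (fcThresholdLog2 < 0 || alpha <= 0 || nTests <= 0)
    stop("thresholds must be positive")
  members <- diff$gene[diff$log2fc >= fcThresholdLog2 &
                         diff$p <= alpha / nTests]
  GeneSignature(members,
                provenance = list(fcThresholdLog2 = fcThresholdLog2,
                                  alpha = alpha, nTests = nTests,
                                  bonferroniCutoff = alpha / nTests))
}

#' Score samples by mean signature expression
#'
#' The score of a sample is the mean of `log2(x + pseudocount)` over the
#' signature genes.
#'
#' @param study an [ExpressionStudy].
#' @param signature a [GeneSignature] or character vector of gene ids.
#' @param pseudocount added before the log2 transform (default 1).
#' @param strict error (default) or drop-with-warning when signature genes
#'   are missing from the study.
#' @return A named numeric vector of per-sample scores.
#' @export
scoreSamples <- function(study, signature, pseudocount = 1, strict = TRUE) {
  genes <- if (is(signature, "GeneSignature")) geneIds(signature)
           else as.character(signature)
  if (length(genes) == 0) stop("empty signature")
  missing <- setdiff(genes, geneIds(study))
  if (length(missing)) {
    if (strict)
      stop("signature gene(s) missing from study: ",
           paste(missing, collapse = ", "))
    warning("dropping signature gene(s) missing from study: ",
            paste(missing, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, missing)
    if (length(genes) == 0) stop("no signature genes left after dropping")
  }
  x <- log2p(exprValues(study)[genes, , drop = FALSE], pseudocount)
  colMeans(x)
}

#' Bin samples into score strata
#'
#' Samples are ranked by descending score (ties broken by ascending sample
#' id, deterministically). Schemes:
#' * `"tertile"`: top `floor(N/3)` samples are `high`, bottom `floor(N/3)`
#'   are `low`, the remainder `mid`.
#' * `"half"`: top `floor(N/2)` are `high`, the rest `low`.
#' * `"p33"`: as `tertile` but the middle third is left unassigned
#'   (stratum `NA`).
#'
#' @param scores named numeric vector of per-sample scores.
#' @param scheme `"tertile"`, `"half"` or `"p33"`.
#' @return A `data.frame` with columns `sample`, `score`, `stratum` and a
#'   `"scheme"` attribute; strata are disjoint by construction.
#' @export
binByScore <- function(scores, scheme = c("tertile", "half", "p33")) {
  scheme <- match.arg(scheme)
  if (anyNA(scores)) stop("scores contain NA")
  n <- length(scores)
  if (n < if (scheme == "half") 2 else 3)
    stop("too few samples (", n, ") for scheme '", scheme, "'")
  ord <- order(-scores, names(scores))
  stratum <- rep(NA_character_, n)
  if (scheme == "half") {
    k <- floor(n / 2)
    stratum[ord[seq_len(k)]] <- "high"
    stratum[ord[(k + 1):n]] <- "low"
  } else {
    k <- floor(n / 3)
    stratum[ord[seq_len(k)]] <- "high"
    stratum[ord[(n - k + 1):n]] <- "low"
    if (scheme == "tertile" && n > 2 * k)
      stratum[ord[(k + 1):(n - k)]] <- "mid"
  }
  out <- data.frame(sample = names(scores), score = unname(scores),
                    stratum = stratum, stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  out
}

#' Nested two-level 33-percentile binning
#'
#' Samples are first binned by the outer score (`p33` scheme: top and
#' bottom thirds); within each outer bin, the inner score is binned the
#' same way using only within-bin ranks. The four assigned cells are
#' labeled `<outerHigh|outerLow>.<innerHigh|innerLow>`; middle thirds at
#' either level remain unassigned.
#'
#' @param scoresOuter,scoresInner named numeric score vectors covering the
#'   same samples.
#' @return A `data.frame` with columns `sample`, `outer`, `inner`, `cell`.
#' @export
nestedBins <- function(scoresOuter, scoresInner) {
  if (!setequal(names(scoresOuter), names(scoresInner)))
    stop("outer and inner score tables must cover the same samples")
  outer <- binByScore(scoresOuter, scheme = "p33")
  inner <- rep(NA_character_, nrow(outer))
  names(inner) <- outer$sample
  for (lev in c("high", "low")) {
    members <- outer$sample[!is.na(outer$stratum) & outer$stratum == lev]
    if (length(members) >= 3) {
      b <- binByScore(scoresInner[members], scheme = "p33")
      inner[b$sample] <- b$stratum
    }
  }
  cell <- ifelse(is.na(outer$stratum) | is.na(inner), NA_character_,
                 paste0("outer", toupper(substring(outer$stratum, 1, 1)),
                        substring(outer$stratum, 2), ".inner",
                        toupper(substring(inner, 1, 1)), substring(inner, 2)))
  data.frame(sample = outer$sample, outer = outer$stratum,
             inner = unname(inner[outer$sample]), cell = cell,
             stringsAsFactors = FALSE)
}
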