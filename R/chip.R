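## Peak-to-gene annotation by closest TSS, bound-gene calling, binomial
## binding enrichment of a signature, and second-mark co-localization.

## 0-based anchor position of each peak: the summit when the narrowPeak
## `peak` column is present and >= 0, else the interval center.
peak_anchors <- function(peaks) {
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  anchor <- floor((s0 + e0) / 2)
  pk <- S4Vectors::mcols(peaks)$peak
  if (!is.null(pk)) {
    use <- !is.na(pk) & pk >= 0L
    anchor[use] <- s0[use] + pk[use]
  }
  anchor
}

#' Annotate peaks with the closest gene TSS
#'
#' Each peak is anchored at its summit (narrowPeak `peak` column, when
#' present and non-negative) or otherwise at its center, and assigned the
#' gene with the minimal `|anchor - TSS|` distance on the same chromosome.
#' Equidistant ties resolve to the gene with the lower TSS coordinate.
#' Peaks on chromosomes without any gene are flagged unannotated
#' (`gene = NA`).
#'
#' @param peaks a `GRanges` of peaks (see [readIntervals()]).
#' @param loci a gene-locus `data.frame` (see [readLoci()]).
#' @return A `data.frame` with one row per peak: `peak` (name, or index
#'   when unnamed), `chrom`, `anchor` (0-based), `gene`, `distance`
#'   (anchor - TSS, positive downstream of the TSS coordinate).
#' @export
annotatePeaks <- function(peaks, loci) {
  if (nrow(loci) == 0) stop("empty gene-locus table")
  if (length(peaks) == 0) stop("empty peak set")
  anchor <- peak_anchors(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  nm <- S4Vectors::mcols(peaks)$name
  if (is.null(nm)) nm <- as.character(seq_along(peaks))
  gene <- rep(NA_character_, length(peaks))
  dist <- rep(NA_real_, length(peaks))
  for (ch in unique(chrom)) {
    gl <- loci[loci$chrom == ch, , drop = FALSE]
    pidx <- which(chrom == ch)
    if (nrow(gl) == 0) next
    ## sort by (tss, gene) so that among equal TSSs the choice is stable;
    ## ties in distance resolve to the lower TSS (the left neighbor)
    gl <- gl[order(gl$tss, gl$gene), , drop = FALSE]
    a <- anchor[pidx]
    left <- findInterval(a, gl$tss)
    right <- pmin(left + 1L, nrow(gl))
    left <- pmax(left, 1L)
    dl <- abs(a - gl$tss[left])
    dr <- abs(a - gl$tss[right])
    use_left <- dl <= dr   # tie -> left neighbor = lower TSS
    best <- ifelse(use_left, left, right)
    gene[pidx] <- gl$gene[best]
    dist[pidx] <- a - gl$tss[best]
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)),
            " peak(s) on chromosomes without genes left unannotated",
            call. = FALSE)
  data.frame(peak = nm, chrom = chrom, anchor = anchor, gene = gene,
             distance = dist, stringsAsFactors = FALSE)
}

#' Genes bound by at least one peak
#'
#' A gene is "bound" when it is the closest gene of at least one peak,
#' optionally restricted to peaks within `maxDistance` bp of its TSS.
#'
#' @param annotation a peak annotation from [annotatePeaks()].
#' @param maxDistance optional cap on `|distance|`; `NULL` (default) keeps
#'   pure closest-gene semantics.
#' @return A character vector of bound gene ids (sorted, unique).
#' @export
boundGenes <- function(annotation, maxDistance = NULL) {
  if (nrow(annotation) == 0) return(character())
  keep <- !is.na(annotation$gene)
  if (!is.null(maxDistance))
    keep <- keep & abs(annotation$distance) <= maxDistance
  sort(unique(annotation$gene[keep]))
}

#' Binomial enrichment of binding among signature genes
#'
#' Tests whether the fraction of signature genes that are bound exceeds the
#' background bound fraction `p0` with an exact one-sided binomial tail
#' `P(X >= k | n, p0)`. By default `p0` is derived from the data: the bound
#' fraction of the universe after excluding the signature genes.
#'
#' @param signature a [GeneSignature] or character vector of gene ids; must
#'   be a subset of the universe genes.
#' @param bound character vector of bound gene ids (see [boundGenes()]).
#' @param universe a gene-locus `data.frame` (see [readLoci()]) or a
#'   character vector of all annotated genes.
#' @param p0 optional background bound fraction overriding the derived one.
#' @return A [BindingEnrichment-class] object.
#' @export
bindingEnrichment <- function(signature, bound, universe, p0 = NULL) {
  sig <- if (is(signature, "GeneSignature")) geneIds(signature)
         else unique(as.character(signature))
  uni <- if (is.data.frame(universe)) universe$gene
         else unique(as.character(universe))
  outside <- setdiff(sig, uni)
  if (length(outside))
    stop("signature gene(s) not in the universe: ",
         paste(outside, collapse = ", "))
  k <- length(intersect(sig, bound))
  n <- length(sig)
  if (is.null(p0)) {
    bg <- setdiff(uni, sig)
    if (length(bg) == 0) stop("no background genes left to derive p0")
    p0 <- length(intersect(bound, bg)) / length(bg)
  }
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate background bound fraction p0 = ", p0,
         "; supply a p0 strictly between 0 and 1")
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  new("BindingEnrichment", k = as.integer(k), n = as.integer(n),
      p0 = p0, p.value = p)
}

#' Co-localization of peaks with a second mark
#'
#' A peak counts as co-localized when it shares at least one base with any
#' interval of the second mark (direct overlap, half-open file semantics).
#'
#' @param peaks a `GRanges` of peaks under consideration (e.g. the TF peaks
#'   at signature genes).
#' @param secondMark a `GRanges` of the second mark (e.g. H3K27ac peaks).
#' @return An [OverlapSummary-class] object.
#' @export
colocalization <- function(peaks, secondMark) {
  if (length(peaks) == 0) stop("empty peak set")
  ## disjoint chromosome sets are a valid zero-overlap case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, secondMark, minoverlap = 1L))
  new("OverlapSummary", considered = length(peaks),
      overlapping = sum(hits > 0),
      fraction = sum(hits > 0) / length(peaks))
}
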