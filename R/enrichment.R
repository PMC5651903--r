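## Preranked GSEA: signal-to-noise ranking, weighted Kolmogorov-Smirnov
## enrichment score, permutation null with NES and the pooled-NES FDR, plus
## the hypergeometric over-representation test.

#' Rank genes by a two-group signal-to-noise metric
#'
#' Per gene, on `log2(x + pseudocount)` values:
#' `(mean_high - mean_low) / (sd_high + sd_low + eps)`. Genes are returned
#' in descending metric order, ties broken by ascending gene id.
#'
#' @param study an [ExpressionStudy].
#' @param strata optional stratum assignment ([binByScore()] `data.frame`
#'   or named character vector); defaults to the study's group labels.
#' @param groups the two group labels, numerator first (default
#'   `c("high", "low")`).
#' @param pseudocount added before the log2 transform (default 1).
#' @param eps guard added to the denominator (default `1e-8`); a gene
#'   constant in both groups gets metric 0.
#' @return A `data.frame` with columns `gene`, `metric`, ordered for
#'   [enrichmentScore()] and [gsea()].
#' @export
rankGenes <- function(study, strata = NULL, groups = c("high", "low"),
                      pseudocount = 1, eps = 1e-8) {
  grp <- resolve_groups(study, strata)
  x <- log2p(exprValues(study), pseudocount)
  hi <- which(grp == groups[1]); lo <- which(grp == groups[2])
  if (length(hi) < 2 || length(lo) < 2)
    stop("need >= 2 samples per group (got ", length(hi), " '", groups[1],
         "', ", length(lo), " '", groups[2], "')")
  metric <- s2n(x[, hi, drop = FALSE], x[, lo, drop = FALSE], eps)
  ord <- order(-metric, rownames(x))
  data.frame(gene = rownames(x)[ord], metric = unname(metric[ord]),
             stringsAsFactors = FALSE)
}

resolve_groups <- function(study, strata) {
  if (is.null(strata)) {
    grp <- sampleGroup(study)
    if (is.null(grp)) stop("no strata given and study has no group labels")
    return(grp)
  }
  if (is.data.frame(strata))
    return(setNames(strata$stratum, strata$sample)[sampleIds(study)])
  strata[sampleIds(study)]
}

s2n <- function(xh, xl, eps = 1e-8) {
  sh <- row_means_vars(xh); sl <- row_means_vars(xl)
  (sh$mean - sl$mean) / (sqrt(sh$var) + sqrt(sl$var) + eps)
}

#' Weighted-KS enrichment score of one gene set
#'
#' Walking down the ranked list, genes in the set increment a running sum by
#' `|metric|^weight / sum_hits(|metric|^weight)` and genes outside it
#' decrement it by `1 / (N - N_hits)`. The enrichment score is the signed
#' maximum deviation of the running sum from zero (ties between equal
#' positive and negative deviations resolve positive).
#'
#' @param ranked a ranked list from [rankGenes()] (columns `gene`,
#'   `metric`, descending).
#' @param geneSet character vector of member gene ids; must intersect the
#'   ranked list.
#' @param weight exponent on the metric (default 1; `0` gives the classic
#'   unweighted KS statistic).
#' @return A list with `es` (numeric in `[-1, 1]`) and `running` (the full
#'   running-sum vector, one entry per ranked gene).
#' @export
enrichmentScore <- function(ranked, geneSet, weight = 1) {
  hit <- ranked$gene %in% geneSet
  if (!any(hit)) stop("gene set does not intersect the ranked list")
  n <- nrow(ranked)
  k <- sum(hit)
  w <- abs(ranked$metric)^weight
  denom_hit <- sum(w[hit])
  inc <- numeric(n)
  if (denom_hit == 0) {
    inc[hit] <- 1 / k  # all hit metrics zero: fall back to equal weights
  } else {
    inc[hit] <- w[hit] / denom_hit
  }
  if (k < n) inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  ## positive/negative deviations equal within numerical noise resolve
  ## positive, so the sign is stable under reordering of the accumulation
  es_pos <- max(running)
  es_neg <- min(running)
  es <- if (es_pos >= -es_neg - 1e-12) es_pos else es_neg
  list(es = es, running = running)
}

## O(k) enrichment score from hit positions in the ranked list.
## pos: sorted 1-based hit positions; whit: |metric|^weight at those
## positions (same order). Agrees exactly with enrichmentScore().
fast_es <- function(pos, whit, n) {
  k <- length(pos)
  denom_hit <- sum(whit)
  cum <- if (denom_hit == 0) seq_len(k) / k else cumsum(whit) / denom_hit
  if (k == n) return(max(cum))
  miss <- (pos - seq_len(k)) / (n - k)
  at_hit <- cum - miss
  before_hit <- c(0, cum[-k]) - miss
  es_pos <- max(at_hit)
  es_neg <- min(before_hit, 0)
  if (es_pos >= -es_neg - 1e-12) es_pos else es_neg
}

## Group-mean/sd matrices for all permutations at once via cross-products.
## x: genes x samples (log2 scale); ind: samples x nPerm 0/1 indicator of
## group-1 membership, with constant column sums n1.
s2n_matrix <- function(x, ind, eps = 1e-8) {
  n1 <- sum(ind[, 1]); n2 <- nrow(ind) - n1
  tot <- rowSums(x); tot2 <- rowSums(x^2)
  s1 <- x %*% ind; s1sq <- (x^2) %*% ind
  m1 <- s1 / n1
  m2 <- (tot - s1) / n2
  v1 <- (s1sq - n1 * m1^2) / (n1 - 1)
  v2 <- ((tot2 - s1sq) - n2 * m2^2) / (n2 - 1)
  (m1 - m2) / (sqrt(pmax(v1, 0)) + sqrt(pmax(v2, 0)) + eps)
}

#' Gene set enrichment analysis with a permutation null
#'
#' Computes the weighted-KS enrichment score ([enrichmentScore()]) of every
#' gene set on the observed two-group signal-to-noise ranking
#' ([rankGenes()]), builds a null distribution from `nPerm` permutations —
#' phenotype (group-label) permutations by default, random gene sets of
#' matched size (`permType = "gene_set"`) as fallback — and reports per set:
#'
#' * `nes`: ES divided by the mean |null ES| of matching sign;
#' * `pval`: the matching-sign null tail fraction at the observed ES;
#' * `padj`: the canonical pooled-NES false-discovery estimate — the ratio
#'   of the null and observed fractions of NES values at least as extreme,
#'   computed within each sign and clamped to `[0, 1]`;
#' * `leadingEdge`: the member genes at or before the running-sum peak
#'   (after it, for negative ES), comma-separated.
#'
#' Groups with fewer than 7 samples per arm trigger an automatic switch to
#' gene-set permutation with a warning. Results are deterministic given
#' `seed`.
#'
#' @inheritParams rankGenes
#' @param collection named list of gene sets (see [readGmt()]).
#' @param nPerm number of permutations (default 1000; below 100 warns).
#' @param seed integer seed for the permutation null.
#' @param permType `"phenotype"` (default) or `"gene_set"`.
#' @param weight metric exponent (default 1).
#' @param minSize,maxSize set-size filter applied after intersecting each
#'   set with the measured genes (defaults 15 and 500).
#' @return A `data.frame`, one row per retained set, ordered by decreasing
#'   `nes`: `set`, `size`, `es`, `nes`, `pval`, `padj`, `leadingEdge`.
#' @export
gsea <- function(study, strata = NULL, collection, nPerm = 1000, seed = 1,
                 permType = c("phenotype", "gene_set"),
                 groups = c("high", "low"), weight = 1, minSize = 15,
                 maxSize = 500, pseudocount = 1, eps = 1e-8) {
  permType <- match.arg(permType)
  if (length(collection) == 0) stop("empty gene set collection")
  if (nPerm < 100)
    warning("nPerm < 100 gives unstable p-values and FDR estimates",
            call. = FALSE)
  grp <- resolve_groups(study, strata)
  keep <- !is.na(grp) & grp %in% groups
  x <- log2p(exprValues(study)[, keep, drop = FALSE], pseudocount)
  grp <- grp[keep]
  n1 <- sum(grp == groups[1]); n2 <- sum(grp == groups[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  if (permType == "phenotype" && min(n1, n2) < 7) {
    warning("fewer than 7 samples per arm; switching to gene_set permutation",
            call. = FALSE)
    permType <- "gene_set"
  }

  genes <- rownames(x)
  n <- length(genes)
  sets <- lapply(collection, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  keep_sets <- sizes >= minSize & sizes <= maxSize
  if (!any(keep_sets))
    stop("no gene set within the size window [", minSize, ", ", maxSize, "]")
  sets <- sets[keep_sets]
  set_idx <- lapply(sets, match, table = genes)

  ## observed ranking and ES
  metric <- s2n(x[, grp == groups[1], drop = FALSE],
                x[, grp == groups[2], drop = FALSE], eps)
  ord <- order(-metric, genes)
  rankpos <- integer(n); rankpos[ord] <- seq_len(n)
  w_abs <- abs(metric)^weight
  obs <- vapply(set_idx, function(idx) {
    o <- order(rankpos[idx])
    fast_es(rankpos[idx][o], w_abs[idx][o], n)
  }, numeric(1))
  le <- leading_edges(set_idx, obs, rankpos, w_abs, genes, n)

  ## permutation null
  m <- length(sets)
  null_es <- withr::with_seed(seed, {
    if (permType == "phenotype") {
      out <- matrix(NA_real_, m, nPerm)
      ind <- vapply(seq_len(nPerm), function(j) {
        v <- numeric(length(grp)); v[sample.int(length(grp), n1)] <- 1; v
      }, numeric(length(grp)))
      pm <- s2n_matrix(x, ind, eps)
      for (j in seq_len(nPerm)) {
        mj <- pm[, j]
        oj <- order(-mj, genes)
        rp <- integer(n); rp[oj] <- seq_len(n)
        wj <- abs(mj)^weight
        for (s in seq_len(m)) {
          idx <- set_idx[[s]]
          o <- order(rp[idx])
          out[s, j] <- fast_es(rp[idx][o], wj[idx][o], n)
        }
      }
      out
    } else {
      w_sorted <- w_abs[ord]
      out <- matrix(NA_real_, m, nPerm)
      for (s in seq_len(m)) {
        k <- length(set_idx[[s]])
        for (j in seq_len(nPerm)) {
          pos <- sort(sample.int(n, k))
          out[s, j] <- fast_es(pos, w_sorted[pos], n)
        }
      }
      out
    }
  })

  ## normalization and significance
  mean_pos <- apply(null_es, 1, function(v) mean(v[v >= 0]))
  mean_neg <- apply(null_es, 1, function(v) mean(abs(v[v < 0])))
  norm1 <- function(e, s) {
    d <- if (e >= 0) mean_pos[s] else mean_neg[s]
    if (is.na(d) || d == 0) NA_real_ else e / d
  }
  nes <- vapply(seq_len(m), function(s) norm1(obs[s], s), numeric(1))
  pval <- vapply(seq_len(m), function(s) {
    v <- null_es[s, ]
    if (obs[s] >= 0) {
      pos <- v[v >= 0]
      if (length(pos) == 0) NA_real_ else mean(pos >= obs[s])
    } else {
      neg <- v[v < 0]
      if (length(neg) == 0) NA_real_ else mean(neg <= obs[s])
    }
  }, numeric(1))
  nes_null <- null_es
  for (s in seq_len(m))
    nes_null[s, ] <- vapply(null_es[s, ], norm1, numeric(1), s = s)
  padj <- fdr_pooled_nes(nes, nes_null)

  out <- data.frame(set = names(sets), size = lengths(sets), es = unname(obs),
                    nes = nes, pval = pval, padj = padj,
                    leadingEdge = le, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$nes), , drop = FALSE]
}

## Canonical pooled-NES FDR: for each observed NES, the fraction of the
## pooled null NES at least as extreme (within its sign), divided by the
## fraction of observed NES at least as extreme, clamped to [0, 1].
fdr_pooled_nes <- function(nes, nes_null) {
  pool <- nes_null[is.finite(nes_null)]
  pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
  obs_pos <- nes[!is.na(nes) & nes >= 0]; obs_neg <- nes[!is.na(nes) & nes < 0]
  vapply(nes, function(e) {
    if (is.na(e)) return(NA_real_)
    if (e >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= e) else 0
      den <- mean(obs_pos >= e)
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= e) else 0
      den <- mean(obs_neg <= e)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
}

leading_edges <- function(set_idx, obs, rankpos, w_abs, genes, n) {
  vapply(seq_along(set_idx), function(s) {
    idx <- set_idx[[s]]
    o <- order(rankpos[idx])
    pos <- rankpos[idx][o]
    whit <- w_abs[idx][o]
    k <- length(pos)
    denom_hit <- sum(whit)
    cum <- if (denom_hit == 0) seq_len(k) / k else cumsum(whit) / denom_hit
    gs <- genes[idx][o]
    if (k == n) return(paste(gs, collapse = ","))
    miss <- (pos - seq_len(k)) / (n - k)
    if (obs[s] >= 0) {
      peak <- which.max(cum - miss)
      paste(gs[seq_len(peak)], collapse = ",")
    } else {
      peak <- which.min(c(0, cum[-k]) - miss)
      paste(gs[peak:k], collapse = ",")
    }
  }, character(1))
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, the one-sided probability of observing at
#' least the seen overlap between the query set and the term, drawing the
#' query size without replacement from the universe.
#'
#' @param query character vector (or [GeneSignature]) of query gene ids;
#'   genes outside the universe are dropped with a warning.
#' @param annotation named list of term gene sets; term members outside the
#'   universe are dropped with a warning.
#' @param universe character vector of all testable gene ids.
#' @return A `data.frame` with one row per term: `term`, `overlap`,
#'   `querySize`, `termSize`, `universeSize`, `p` (one-sided
#'   `P(X >= overlap)`), ordered by increasing `p`.
#' @export
hypergeomEnrichment <- function(query, annotation, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  if (is(query, "GeneSignature")) query <- geneIds(query)
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping query gene(s) outside the universe: ",
            paste(outside, collapse = ", "), call. = FALSE)
    query <- intersect(query, universe)
  }
  dropped_terms <- sum(vapply(annotation, function(s)
    length(setdiff(s, universe)) > 0, logical(1)))
  if (dropped_terms > 0)
    warning(dropped_terms,
            " term(s) had members outside the universe; they were dropped",
            call. = FALSE)
  res <- lapply(names(annotation), function(nm) {
    term <- intersect(unique(annotation[[nm]]), universe)
    k <- length(intersect(query, term))
    p <- phyper(k - 1, length(term), length(universe) - length(term),
                length(query), lower.tail = FALSE)
    data.frame(term = nm, overlap = k, querySize = length(query),
               termSize = length(term), universeSize = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}
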