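# Small in-code fixtures and independent brute-force oracles used across
# the suite. Oracles are deliberately written as plain loops/enumeration,
# independent of the package's implementation paths.

tiny_study <- function() {
  m <- rbind(gA = c(3, 7, 15, 1, 3),
             gB = c(1, 1, 1, 1, 1),
             gC = c(10, 20, 30, 40, 50))
  colnames(m) <- paste0("s", 1:5)
  ExpressionStudy(m, group = c("tumor", "tumor", "tumor", "normal", "normal"))
}

random_survival <- function(n, tie_rate = 0.5, seed = 1) {
  withr::with_seed(seed, {
    tm <- rexp(n, 0.05)
    if (tie_rate > 0) tm <- ceiling(tm)  # force tied event/censor times
    data.frame(sample = sprintf("s%03d", seq_len(n)),
               time = pmax(tm, 0.5),
               event = rbinom(n, 1, 0.7))
  })
}

# step-by-step weighted-KS running sum, written as an explicit loop
brute_es <- function(metrics, is_hit, weight = 1) {
  n <- length(metrics)
  k <- sum(is_hit)
  w <- abs(metrics)^weight
  denom_hit <- sum(w[is_hit])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cur <- cur + if (denom_hit == 0) 1 / k else w[i] / denom_hit
    } else {
      cur <- cur - 1 / (n - k)
    }
    run[i] <- cur
  }
  es_pos <- max(run)
  es_neg <- min(run)
  list(es = if (es_pos >= -es_neg - 1e-12) es_pos else es_neg, running = run)
}

# all-pairs closest-TSS scan with the lower-TSS tie rule
brute_closest <- function(anchor, chrom, loci) {
  best_gene <- NA_character_
  best_dist <- NA_real_
  for (i in seq_len(nrow(loci))) {
    if (loci$chrom[i] != chrom) next
    d <- anchor - loci$tss[i]
    better <- is.na(best_dist) || abs(d) < abs(best_dist) ||
      (abs(d) == abs(best_dist) && loci$tss[i] < loci$tss[best_idx])
    if (better) {
      best_gene <- loci$gene[i]
      best_dist <- d
      best_idx <- i
    }
  }
  list(gene = best_gene, distance = best_dist)
}

# naive O(n*m) half-open overlap count: [s1,e1) and [s2,e2) overlap iff
# s1 < e2 and s2 < e1
brute_overlap_count <- function(a0, b0) {
  hits <- 0L
  for (i in seq_len(nrow(a0))) {
    for (j in seq_len(nrow(b0))) {
      if (a0$start[i] < b0$end[j] && b0$start[j] < a0$end[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# GRanges from 0-based half-open coordinates, with optional narrowPeak mcols
np_gr <- function(chrom, start0, end0, name = NULL, summit = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(summit)) S4Vectors::mcols(gr)$peak <- as.integer(summit)
  gr
}

granges_from0 <- function(df0) {
  GenomicRanges::GRanges(df0$chrom,
                         IRanges::IRanges(start = df0$start + 1L,
                                          end = df0$end))
}
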