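test_that("signal-to-noise ranking matches hand arithmetic", {
  # high {4,8}, low {1,1}: log2(x+1) {2.3219, 3.1699} vs {1, 1}
  m <- rbind(g1 = c(4, 8, 1, 1), g2 = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  es <- ExpressionStudy(m, group = c("high", "high", "low", "low"))
  rk <- rankGenes(es)
  h <- log2(c(4, 8) + 1)
  expected <- (mean(h) - 1) / (sd(h) + 0 + 1e-8)
  expect_equal(rk$metric[rk$gene == "g1"], expected)
  # constant gene in both groups: metric 0
  expect_equal(rk$metric[rk$gene == "g2"], 0)
  # identical groups: all metrics 0
  es2 <- ExpressionStudy(m[, c(1, 2, 1, 2)] |>
                           (\(x) {colnames(x) <- paste0("t", 1:4); x})(),
                         group = c("high", "high", "low", "low"))
  expect_true(all(rankGenes(es2)$metric == 0))
})

test_that("enrichment score reproduces the worked running-sum example", {
  rk <- data.frame(gene = paste0("g", 1:4), metric = c(3, 2, 1, 0.5))
  r <- enrichmentScore(rk, c("g1", "g3"))
  expect_equal(r$running, c(0.75, 0.25, 0.50, 0))
  expect_equal(r$es, 0.75)
  # degenerate unweighted limits
  expect_equal(enrichmentScore(rk, "g1", weight = 0)$es, 1)
  # bottom-gene singleton set: N-1 misses each worth 1/(N-1) reach -1
  # exactly before the final hit returns the sum to zero
  n <- 50
  rkn <- data.frame(gene = sprintf("g%03d", 1:n), metric = seq(n, 1))
  es_bottom <- enrichmentScore(rkn, sprintf("g%03d", n), weight = 0)$es
  expect_lte(es_bottom, -(n - 1) / n)
  expect_equal(es_bottom, -1)
  expect_error(enrichmentScore(rk, "absent"), "intersect")
})

test_that("enrichment score equals exhaustive brute force on all small subsets", {
  withr::with_seed(21, {
    for (n in c(4, 6, 8)) {
      metrics <- sort(round(rnorm(n, 0, 2), 2), decreasing = TRUE)
      rk <- data.frame(gene = sprintf("g%02d", 1:n), metric = metrics)
      for (mask in 1:(2^n - 1)) {
        hit <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
        set <- rk$gene[hit]
        for (w in c(0, 1, 1.5)) {
          got <- enrichmentScore(rk, set, weight = w)
          want <- brute_es(metrics, hit, weight = w)
          expect_equal(got$es, want$es, tolerance = 1e-12)
          expect_equal(got$running, want$running, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("enrichment score is invariant to uniform metric rescaling at weight 1", {
  withr::with_seed(22, {
    rk <- data.frame(gene = sprintf("g%03d", 1:100),
                     metric = sort(rnorm(100), decreasing = TRUE))
    set <- sample(rk$gene, 15)
    base <- enrichmentScore(rk, set)$es
    for (lambda in c(0.1, 7, 1000)) {
      rk2 <- rk; rk2$metric <- rk2$metric * lambda
      expect_equal(enrichmentScore(rk2, set)$es, base, tolerance = 1e-12)
    }
  })
})

test_that("gsea recovers the planted set, deterministically", {
  g <- genGseaStudy(seed = 1)
  res <- gsea(g$study, collection = g$collection, nPerm = 200, seed = 42)
  expect_equal(res$set[1], "EMT")         # top NES
  expect_lt(res$padj[res$set == "EMT"], 0.05)
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  # the observed ES column equals the single-set scorer on the same ranking
  rk <- rankGenes(g$study)
  i <- match("SET10", res$set)
  expect_equal(res$es[i],
               enrichmentScore(rk, g$collection[["SET10"]])$es,
               tolerance = 1e-12)
  # determinism
  res2 <- gsea(g$study, collection = g$collection, nPerm = 200, seed = 42)
  expect_identical(res$padj, res2$padj)
  expect_identical(res$pval, res2$pval)
})

test_that("gsea nominal p-values are calibrated under a label null", {
  ps <- unlist(lapply(1:5, function(s) {
    g0 <- genGseaStudy(nGenes = 1000, nSets = 20, setSize = 50,
                       nHigh = 40, nLow = 40, shiftLog2 = 0, seed = s)
    gsea(g0$study, collection = g0$collection, nPerm = 200,
         seed = 100 + s)$pval
  }))
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 0.03)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("small arms fall back to gene-set permutation with a warning", {
  g <- genGseaStudy(nGenes = 300, nSets = 5, setSize = 30,
                    nHigh = 5, nLow = 5, seed = 3)
  expect_warning(res <- gsea(g$study, collection = g$collection,
                             nPerm = 150, seed = 1),
                 "gene_set")
  expect_equal(res$set[1], "EMT")
  expect_warning(gsea(g$study, collection = g$collection, nPerm = 50,
                      seed = 1, permType = "gene_set"), "nPerm")
})

test_that("gsea set ranking agrees with fgsea on simulated draws", {
  skip_if_not_installed("fgsea")
  rho <- vapply(1:10, function(s) {
    g <- genGseaStudy(nGenes = 2000, nSets = 25, setSize = 60,
                      nHigh = 60, nLow = 60, seed = s)
    res <- gsea(g$study, collection = g$collection, nPerm = 200, seed = s)
    rk <- rankGenes(g$study)
    stats <- setNames(rk$metric, rk$gene)
    fg <- suppressWarnings(
      fgsea::fgsea(g$collection, stats, minSize = 15, maxSize = 500,
                   nPermSimple = 1000))
    both <- merge(res[, c("set", "nes")],
                  data.frame(set = fg$pathway, fnes = fg$NES), by = "set")
    cor(both$nes, both$fnes, method = "spearman")
  }, numeric(1))
  expect_true(all(rho >= 0.9))
})

test_that("hypergeometric test equals exact combinatorial enumeration", {
  # universe 10, term 5, query 4, overlap 4 -> 5/210
  res <- hypergeomEnrichment(paste0("g", 1:4), list(T = paste0("g", 1:5)),
                             paste0("g", 1:10))
  expect_equal(res$p, 5 / 210)
  # brute-force enumeration oracle over all overlap counts
  enum_p <- function(N, K, n, k) {
    num <- 0
    for (x in k:min(K, n)) num <- num + choose(K, x) * choose(N - K, n - x)
    num / choose(N, n)
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      N <- sample(8:25, 1)
      K <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      uni <- sprintf("u%02d", 1:N)
      term <- sample(uni, K)
      query <- sample(uni, n)
      k <- length(intersect(term, query))
      res <- hypergeomEnrichment(query, list(T = term), uni)
      expect_equal(res$p, enum_p(N, K, n, k), tolerance = 1e-12)
    }
  })
  # trivial bounds
  expect_equal(hypergeomEnrichment("g9", list(T = paste0("g", 1:5)),
                                   paste0("g", 1:10))$p, 1)  # overlap 0
  res <- hypergeomEnrichment(paste0("g", 1:10), list(T = paste0("g", 1:5)),
                             paste0("g", 1:10))
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1)  # query = universe forces the full overlap
  expect_error(hypergeomEnrichment("g1", list(T = "g1"), character()),
               "empty universe")
})
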