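test_that("differential expression matches the pooled-variance hand computation", {
  # tumor linear {3,7,15}, normal {1,3}, pseudocount 1 -> log2 {2,3,4} vs {1,2}
  d <- differentialExpression(tiny_study())
  gA <- d[d$gene == "gA", ]
  expect_equal(gA$log2fc, 1.5)
  expect_equal(gA$t, 1.8)
  expect_equal(gA$df, 3)
  expect_equal(gA$p, 2 * pt(-1.8, 3))
  # constant gene: flagged, t = 0, p = 1
  gB <- d[d$gene == "gB", ]
  expect_true(gB$constant)
  expect_equal(gB$t, 0)
  expect_equal(gB$p, 1)
})

test_that("identical groups give zero fold change and p = 1", {
  m <- rbind(g1 = c(2, 8, 2, 8), g2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  es <- ExpressionStudy(m, group = c("tumor", "tumor", "normal", "normal"))
  d <- differentialExpression(es)
  expect_equal(d$log2fc, c(0, 0))
  expect_equal(d$p, c(1, 1))
  expect_error(differentialExpression(
    ExpressionStudy(m, group = c("tumor", "normal", "normal", "normal"))),
    ">= 2 samples")
})

test_that("signature derivation applies the fold-change and Bonferroni filter", {
  diff <- data.frame(gene = c("gene1", "gene2", "gene3"),
                     log2fc = c(1.5, 2.0, 0.5),
                     p = c(1e-10, 0.04, 1e-10))
  sig <- deriveSignature(diff, fcThresholdLog2 = 1, alpha = 0.05, nTests = 3)
  expect_equal(geneIds(sig), "gene1")  # cutoff p <= 0.05/3
  expect_equal(provenance(sig)$bonferroniCutoff, 0.05 / 3)
  expect_length(deriveSignature(diff, fcThresholdLog2 = Inf), 0)
  expect_warning(sig0 <- deriveSignature(diff[0, ]), "empty")
  expect_length(sig0, 0)
})

test_that("derivation is monotone in both thresholds", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      diff <- data.frame(gene = sprintf("g%03d", 1:100),
                         log2fc = rnorm(100, 1, 1),
                         p = runif(100)^3)
      base <- geneIds(deriveSignature(diff, 0.5, 0.05))
      expect_true(all(geneIds(deriveSignature(diff, 1.0, 0.05)) %in% base))
      expect_true(all(geneIds(deriveSignature(diff, 0.5, 0.01)) %in% base))
    }
  })
})

test_that("derivation recovers exactly the planted signature on simulated studies", {
  for (s in c(1, 2)) {
    r <- genExpressionStudy(seed = s)
    d <- differentialExpression(r$study)
    sig <- deriveSignature(d)
    expect_setequal(geneIds(sig), r$truth$plantedGenes)
    # planted genes sit in the top-right of the volcano
    planted <- d$gene %in% r$truth$plantedGenes
    expect_gt(min(d$log2fc[planted]), 1)
    expect_lt(max(d$p[planted]), 0.05 / 388)
  }
})

test_that("under a global null the Bonferroni filter admits almost nothing", {
  # expected significant genes per dataset <= alpha = 0.05; over 60 null
  # datasets the total is Poisson-ish with mean <= 3
  total <- 0
  for (s in 1:60) {
    r <- genExpressionStudy(nGenes = 200, nTumor = 25, nNormal = 15,
                            nPlanted = 0, seed = s)
    d <- differentialExpression(r$study)
    total <- total + sum(d$p <= 0.05 / 200)
  }
  expect_lte(total, 12)
})

test_that("sample scores are the mean log2(x+pseudocount) over signature genes", {
  m <- rbind(g1 = c(15, 3), g2 = c(3, 1))
  colnames(m) <- c("s1", "s2")
  es <- ExpressionStudy(m)
  expect_equal(scoreSamples(es, "g1"), c(s1 = 4, s2 = 2))
  expect_equal(unname(scoreSamples(es, c("g1", "g2"))["s2"]), 1.5)
  # invariant under gene reordering
  expect_equal(scoreSamples(es, c("g1", "g2")), scoreSamples(es, c("g2", "g1")))
  expect_error(scoreSamples(es, character()), "empty")
  expect_error(scoreSamples(es, c("g1", "gX")), "gX")
  expect_warning(sc <- scoreSamples(es, c("g1", "gX"), strict = FALSE), "gX")
  expect_equal(sc, scoreSamples(es, "g1"))
})

test_that("score binning produces the printed stratum sizes", {
  withr::with_seed(5, {
    sc1093 <- setNames(rnorm(1093), sprintf("s%04d", 1:1093))
    half <- binByScore(sc1093, "half")
    expect_equal(sum(half$stratum == "high"), 546)   # top half of 1093
    expect_equal(sum(half$stratum == "low"), 547)
    sc547 <- setNames(rnorm(547), sprintf("s%04d", 1:547))
    tert <- binByScore(sc547, "tertile")
    expect_equal(sum(tert$stratum == "high"), 182)
    expect_equal(sum(tert$stratum == "low"), 182)
    expect_equal(sum(tert$stratum == "mid"), 183)
    p33 <- binByScore(sc547, "p33")
    expect_equal(sum(is.na(p33$stratum)), 183)
  })
  tiny <- binByScore(c(a = 3, b = 2, c = 1), "tertile")
  expect_equal(tiny$stratum, c("high", "mid", "low"))
})

test_that("binning is a disjoint partition with deterministic tie-breaks", {
  withr::with_seed(6, {
    for (n in c(7, 30, 101)) {
      sc <- setNames(round(rnorm(n), 1), sprintf("s%03d", 1:n))  # many ties
      b <- binByScore(sc, "tertile")
      expect_setequal(b$sample, names(sc))
      expect_false(any(duplicated(b$sample)))
      expect_true(all(table(b$stratum)[c("high", "low")] == floor(n / 3)))
      # ties break by ascending sample id: re-running is identical
      expect_identical(b, binByScore(sc, "tertile"))
      # high scores never rank below low scores
      expect_gte(min(b$score[b$stratum == "high"]),
                 max(b$score[b$stratum == "low"]))
    }
  })
  expect_error(binByScore(c(a = 1, b = NA), "half"), "NA")
})

test_that("nested 33-percentile binning uses only within-bin ranks", {
  so <- setNames(9:1, letters[1:9])
  si <- setNames(c(3, 2, 1, 3, 2, 1, 3, 2, 1), letters[1:9])
  nb <- nestedBins(so, si)
  cells <- table(nb$cell)
  expect_equal(length(cells), 4L)
  expect_true(all(cells == 1))
  expect_equal(nb$cell[nb$sample == "a"], "outerHigh.innerHigh")
  # locality: perturbing inner scores of the outer-low bin does not change
  # the assignments within the outer-high bin
  si2 <- si
  si2[c("g", "h", "i")] <- si2[c("g", "h", "i")] + 100
  nb2 <- nestedBins(so, si2)
  hi <- nb$sample[!is.na(nb$outer) & nb$outer == "high"]
  expect_equal(nb$inner[nb$sample %in% hi], nb2$inner[nb2$sample %in% hi])
  expect_error(nestedBins(so, si[-1]), "same samples")
  # independent scores give floor-balanced cells
  withr::with_seed(8, {
    so_big <- setNames(rnorm(300), sprintf("s%03d", 1:300))
    si_big <- setNames(rnorm(300), sprintf("s%03d", 1:300))
    nbb <- nestedBins(so_big, si_big)
    expect_true(all(table(nbb$cell) == 33))  # floor(100/3) per cell
  })
})
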