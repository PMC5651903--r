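test_that("peak annotation picks the closest TSS with the documented tie rule", {
  loci <- data.frame(gene = c("gNear", "gFar"), chrom = "chr1",
                     tss = c(100, 1000), strand = c("+", "-"))
  # peak [400,600) without summit -> center anchor at 500
  ann <- annotatePeaks(np_gr("chr1", 400, 600), loci)
  expect_equal(ann$gene, "gNear")
  expect_equal(ann$distance, 400)
  # summit overrides the center: [400,1000) centered at 700 but summit at 950
  ann <- annotatePeaks(np_gr("chr1", 400, 1000, summit = 550), loci)
  expect_equal(ann$gene, "gFar")
  expect_equal(ann$distance, -50)
  # anchored exactly on a TSS
  ann <- annotatePeaks(np_gr("chr1", 50, 150), loci)
  expect_equal(ann$distance, 0)
  # equidistant -> lower TSS coordinate
  loci2 <- data.frame(gene = c("gB", "gA"), chrom = "chr1",
                      tss = c(1000, 0), strand = "+")
  ann <- annotatePeaks(np_gr("chr1", 400, 600), loci2)
  expect_equal(ann$gene, "gA")
  # chromosome without genes is flagged unannotated
  expect_warning(
    ann <- annotatePeaks(np_gr(c("chr1", "chrX"), c(400, 400), c(600, 600)),
                         loci), "unannotated")
  expect_true(is.na(ann$gene[2]))
})

test_that("peak annotation equals the all-pairs brute-force scan", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n_genes <- sample(20:200, 1)
      n_peaks <- sample(20:200, 1)
      loci <- data.frame(gene = sprintf("g%03d", 1:n_genes),
                         chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                         tss = sample.int(50000, n_genes),
                         strand = "+")
      s0 <- sample.int(50000, n_peaks)
      width <- sample(50:400, n_peaks, replace = TRUE)
      summit <- ifelse(runif(n_peaks) < 0.5, -1L,
                       sapply(width, function(w) sample.int(w, 1) - 1L))
      peaks <- np_gr(sample(c("chr1", "chr2"), n_peaks, TRUE), s0, s0 + width,
                     name = sprintf("p%03d", 1:n_peaks), summit = summit)
      ann <- annotatePeaks(peaks, loci)
      for (i in seq_len(n_peaks)) {
        want <- brute_closest(ann$anchor[i], ann$chrom[i], loci)
        expect_equal(ann$gene[i], want$gene)
        expect_equal(ann$distance[i], want$distance)
      }
    }
  })
})

test_that("bound-gene calling respects the optional distance cap", {
  loci <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                     tss = c(500, 5000), strand = "+")
  peaks <- np_gr("chr1", c(400, 4800), c(600, 5000))  # anchors 500, 4900
  ann <- annotatePeaks(peaks, loci)
  expect_equal(boundGenes(ann), c("g1", "g2"))
  expect_equal(boundGenes(ann, maxDistance = 50), "g1")
  expect_equal(boundGenes(ann, maxDistance = 0), "g1")
  expect_equal(boundGenes(ann[0, ]), character())
})

test_that("binomial binding enrichment matches the summation oracle", {
  # n = 3, p0 = 0.5, k = 2 -> P(X >= 2) = 4/8
  be <- bindingEnrichment(c("a", "b", "c"), bound = c("a", "b"),
                          universe = letters[1:10], p0 = 0.5)
  expect_equal(be@p.value, 0.5)
  # k = 0 -> p = 1
  expect_equal(bindingEnrichment(c("a", "b"), bound = character(),
                                 universe = letters[1:10], p0 = 0.3)@p.value, 1)
  # dense grid against the direct tail summation, n <= 50
  withr::with_seed(42, {
    for (rep in 1:30) {
      n <- sample(1:50, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.05, 0.95)
      sig <- sprintf("s%02d", 1:n)
      be <- bindingEnrichment(sig, bound = sig[seq_len(k)],
                              universe = c(sig, "bg"), p0 = p0)
      oracle <- sum(vapply(k:n, function(x)
        choose(n, x) * p0^x * (1 - p0)^(n - x), numeric(1)))
      expect_equal(be@p.value, oracle, tolerance = 1e-12)
    }
  })
  expect_error(bindingEnrichment(c("a", "zz"), "a", letters[1:5]), "zz")
  expect_error(bindingEnrichment("a", letters[1:5], letters[1:5]),
               "degenerate")
})

test_that("derived background rate excludes the signature genes", {
  uni <- sprintf("u%02d", 1:20)
  sig <- uni[1:5]
  bound <- c(uni[1:4], uni[6:8])  # 4/5 signature, 3/15 background
  be <- bindingEnrichment(sig, bound, uni)
  expect_equal(be@p0, 3 / 15)
  expect_equal(be@k, 4L)
  expect_equal(be@n, 5L)
})

test_that("co-localization counts direct overlaps with half-open semantics", {
  a <- np_gr("chr1", c(0, 100, 300), c(50, 200, 400))
  # adjacent half-open intervals [0,50) and [50,60) do not overlap
  b <- np_gr("chr1", c(50, 150), c(60, 160))
  ov <- colocalization(a, b)
  expect_equal(ov@overlapping, 1L)
  expect_equal(ov@fraction, 1 / 3)
  expect_equal(colocalization(a, a)@fraction, 1)
  expect_equal(colocalization(a, np_gr("chr2", 0, 1000))@fraction, 0)
  expect_error(colocalization(a[0], b), "empty")
  # random sets against the naive O(n*m) oracle
  withr::with_seed(43, {
    for (rep in 1:5) {
      na <- sample(50:500, 1); nb <- sample(50:500, 1)
      a0 <- data.frame(chrom = "c", start = sample.int(10000, na))
      a0$end <- a0$start + sample(1:50, na, replace = TRUE)
      b0 <- data.frame(chrom = "c", start = sample.int(10000, nb))
      b0$end <- b0$start + sample(1:50, nb, replace = TRUE)
      ov <- colocalization(granges_from0(a0), granges_from0(b0))
      expect_equal(ov@overlapping, brute_overlap_count(a0, b0))
    }
  })
})

test_that("the simulated ChIP scenario reproduces its planted enrichment", {
  c1 <- genChipStudy(seed = 2)
  ann <- annotatePeaks(c1$tfPeaks, c1$loci)
  bound <- boundGenes(ann)
  be <- bindingEnrichment(c1$signatureGenes, bound, c1$loci)
  expect_equal(be@k, 14L)
  expect_equal(be@n, 23L)
  expect_lt(be@p.value, 0.01)
  expect_lt(abs(be@p0 - 0.2), 0.02)
})

test_that("binding p-values are super-uniform when the signature is unenriched", {
  # null variant: the signature's bound count is itself a Binomial(23, 0.2)
  # draw, matching the background rate
  withr::with_seed(44, {
    ks <- rbinom(400, 23, 0.2)
  })
  ps <- vapply(seq_along(ks), function(i) {
    c1 <- genChipStudy(nGenes = 1500, chromLength = 7.5e6,
                       nBoundSignature = ks[i],
                       nAcetylSignature = min(ks[i], 1), seed = 1000 + i)
    ann <- annotatePeaks(c1$tfPeaks, c1$loci)
    bindingEnrichment(c1$signatureGenes, boundGenes(ann), c1$loci)@p.value
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1))
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 400))
})
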