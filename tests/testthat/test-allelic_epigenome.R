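mkConstantTrack <- function(value, chrom = "chr1", len = 100000, bin = 50) {
  gr <- GRanges(chrom, IRanges(seq(1, len, by = bin), width = bin))
  gr$score <- rep(value, length(gr))
  gr
}

test_that("binning reproduces constant tracks and conserves allele sums", {
  sitesGr <- GRanges("chr1", IRanges(c(20000, 50000), width = 400))
  tr <- mkConstantTrack(1.5)
  m <- binSignal(tr, sitesGr)
  expect_equal(dim(m), c(2L, 40L))
  expect_true(all(m == 1.5))
  expect_equal(unname(metagene(m)), rep(1.5, 40))

  mat <- mkConstantTrack(0.7)
  pat <- mkConstantTrack(0.4)
  tot <- mkConstantTrack(1.1)
  expect_equal(binSignal(mat, sitesGr) + binSignal(pat, sitesGr),
               binSignal(tot, sitesGr), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("bin values equal a per-base averaging oracle", {
  set.seed(107)
  # random step-function track with irregular segment widths
  brk <- sort(sample(2000:8000, 60))
  seg <- GRanges("chr1", IRanges(c(1, brk + 1), c(brk, 10000)))
  seg$score <- runif(length(seg), 0, 5)
  sitesGr <- GRanges("chr1", IRanges(4000, 4399))   # midpoint 4199
  m <- binSignal(seg, sitesGr, window = 2000, bin = 50)
  # oracle: expand to per-base values, average each 50-bp bin
  base <- rep(NA_real_, 10000)
  for (i in seq_along(seg)) base[start(seg)[i]:end(seg)[i]] <- seg$score[i]
  mid <- 4199
  off <- seq(-1000, 950, by = 50)
  oracle <- vapply(off, function(o) mean(base[(mid + o + 1):(mid + o + 50)]),
                   0)
  expect_equal(unname(m[1, ]), oracle)

  # translation equivariance: shift sites and track by the same offset
  seg2 <- shift(seg, 1234)
  sites2 <- shift(sitesGr, 1234)
  m2 <- binSignal(seg2, sites2, window = 2000, bin = 50)
  expect_equal(unname(m2[1, ]), unname(m[1, ]))
})

test_that("uncovered bins are missing and edge sites are dropped", {
  tr <- GRanges("chr1", IRanges(1, 500))
  tr$score <- 2
  sitesGr <- GRanges("chr1", IRanges(900, 1100))   # window 0-2000
  m <- binSignal(tr, sitesGr, window = 2000, bin = 50)
  expect_true(any(is.na(m)))
  expect_false(any(m == 0, na.rm = TRUE))

  near <- GRanges("chr1", IRanges(c(300, 5000), width = 100))
  m2 <- binSignal(mkConstantTrack(1, len = 10000), near)
  expect_equal(attr(m2, "dropped"), 1L)   # midpoint 349 < window/2
  expect_equal(nrow(m2), 1L)
})

test_that("site clustering recovers archetypes with stable numbering", {
  set.seed(109)
  nbin <- 40
  flankProfile <- ifelse(abs(seq(-975, 975, by = 50)) <= 250, 0.05, 2.2)
  flat <- rep(0.05, nbin)
  mkRows <- function(profile, n, sd) {
    matrix(rep(profile, each = n), n, nbin) +
      matrix(rnorm(n * nbin, 0, sd), n, nbin)
  }
  m <- rbind(mkRows(flankProfile, 60, 1), mkRows(flat, 60, 1))
  rownames(m) <- sprintf("s%03d", 1:120)
  cl <- clusterSites(m, seed = 3)
  truth <- rep(c(1, 2), each = 60)
  expect_gte(adjustedRandIndex(cl$labels, truth), 0.9)
  # cluster 1 is the flank-enriched archetype under any seed
  for (sd. in c(3, 17)) {
    cl2 <- clusterSites(m, seed = sd.)
    expect_gt(mean(cl2$labels[1:60] == 1), 0.9)
  }
  # all-identical rows: degenerate single cluster, reported
  ident <- matrix(1, 10, nbin,
                  dimnames = list(sprintf("i%02d", 1:10), NULL))
  dg <- clusterSites(ident, seed = 1)
  expect_true(dg$degenerate)
  expect_equal(unique(unname(dg$labels)), 1L)
})

test_that("gene-body z-scores average the standardized track", {
  tr <- mkConstantTrack(3, len = 10000)
  z <- zscoreTrack(tr)
  expect_true(all(z$score == 0))          # constant track standardizes to 0
  genes <- GRanges("chr1", IRanges(1000, 2000))
  genes$gene_id <- "G1"
  expect_equal(geneBodyScore(z, genes)$score, 0)

  # gene covering bins with z values 1 and 3 scores 2
  t2 <- GRanges("chr1", IRanges(c(1, 101), width = 100))
  t2$score <- c(1, 3)
  g2 <- GRanges("chr1", IRanges(1, 200))
  g2$gene_id <- "G2"
  expect_equal(geneBodyScore(t2, g2)$score, 2)
  # uncovered gene omitted and reported
  g3 <- GRanges("chr1", IRanges(5000, 6000))
  g3$gene_id <- "G3"
  res <- geneBodyScore(t2, c(g2, g3))
  expect_equal(attr(res, "omitted"), "G3")
})

test_that("planted maternal H3K27me3 on PEGs is detected", {
  set.seed(113)
  n <- 50
  genes <- GRanges("chr1", IRanges(seq(1000, by = 3000, length.out = 2 * n),
                                   width = 1000))
  genes$gene_id <- sprintf("G%03d", seq_along(genes))
  mkZ <- function(shift) {
    gr <- GRanges("chr1", IRanges(seq(1, 3000 * (2 * n + 1), by = 50),
                                  width = 50))
    gr$score <- rnorm(length(gr), 0, 1)
    hits <- findOverlaps(genes[1:n], gr)
    gr$score[subjectHits(hits)] <- gr$score[subjectHits(hits)] + shift
    gr
  }
  z2x <- mkZ(0)     # 2x: no elevation
  z3x <- mkZ(2)     # 3x: +2 sd on the PEG subset (genes 1..n)
  s2 <- geneBodyScore(z2x, genes[1:n])$score
  s3 <- geneBodyScore(z3x, genes[1:n])$score
  expect_lt(compareGroupsMW(s3, s2)$p, 0.01)
})

test_that("methylation contrast finds the planted paternal offset", {
  set.seed(127)
  n <- 60
  groups <- rep(c("MEG", "PEG", "non_imprinted"), each = n)
  base <- function() matrix(pmin(1, pmax(0, rnorm(3 * n * 40, 0.3, 0.05))),
                            3 * n, 40,
                            dimnames = list(sprintf("st%03d", 1:(3 * n)),
                                            NULL))
  mat <- base()
  pat <- base()
  pat[groups == "MEG", ] <- pat[groups == "MEG", ] + 0.3
  res <- methylationContrast(list(maternal = mat, paternal = pat), groups)
  ba <- res$betweenAlleles
  megRow <- ba[ba$group == "MEG", ]
  expect_lt(megRow$p, 1e-6)
  expect_gt(megRow$meanB, megRow$meanA)   # paternal above maternal
  nonRow <- ba[ba$group == "non_imprinted", ]
  expect_gt(nonRow$p, 0.01)               # identical generating law
  # group means equal a direct averaging oracle
  expect_equal(res$siteMeans$mean[res$siteMeans$allele == "maternal"],
               unname(rowMeans(mat)))
  expect_error(methylationContrast(list(m = mat), groups[1:5]),
               "one entry per site")
})

test_that("metagene of the sum channel is the sum of metagenes", {
  set.seed(131)
  sitesGr <- GRanges("chr1", IRanges(seq(5000, 95000, by = 5000),
                                     width = 300))
  mat <- mkConstantTrack(0, len = 100000)
  mat$score <- runif(length(mat))
  pat <- mkConstantTrack(0, len = 100000)
  pat$score <- runif(length(pat))
  tot <- mat
  tot$score <- mat$score + pat$score
  mm <- binSignal(mat, sitesGr)
  mp <- binSignal(pat, sitesGr)
  mt <- binSignal(tot, sitesGr)
  expect_equal(metagene(mm) + metagene(mp), metagene(mt),
               tolerance = 1e-9)
  se <- signalExperiment(list(maternal = mm, paternal = mp, total = mt),
                         sitesGr)
  expect_equal(SummarizedExperiment::assayNames(se),
               c("maternal", "paternal", "total"))
})
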