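test_that("hypergeometric p equals exhaustive enumeration", {
  expect_equal(hypergeomTest(0, 5, 4, 10), 1)
  expect_equal(hypergeomTest(3, 5, 4, 10), oracleHyperP(3, 5, 4, 10))
  # k = min(n, K): single most-extreme term
  expect_equal(hypergeomTest(4, 5, 4, 10),
               choose(4, 4) * choose(6, 1) / choose(10, 5))
  expect_error(hypergeomTest(6, 5, 4, 10), "inconsistent")
  set.seed(79)
  for (i in 1:50) {
    N <- sample(5:25, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeomTest(k, n, K, N), oracleHyperP(k, n, K, N),
                 label = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
    expect_equal(hypergeomTest(k, n, K, N, tail = "under"),
                 1 - (if (k == min(n, K)) 0 else
                   oracleHyperP(k + 1, n, K, N)))
  }
})

test_that("TF family enrichment normalizes and filters as specified", {
  fams <- setNames(c(rep("MADS", 10), rep("WRKY", 85), rep("TINY", 5)),
                   sprintf("TF%03d", 1:100))
  targets <- c(sprintf("TF%03d", 1:5), sprintf("TF%03d", 11:25))
  res <- tfFamilyEnrichment(targets, fams)
  expect_false("TINY" %in% res$family)     # exactly 5 members: excluded
  mads <- res[res$family == "MADS", ]
  expect_equal(mads$log2fc, log2((5 / 20) / (10 / 100)))  # log2 2.5
  expect_equal(mads$p, oracleHyperP(5, 20, 10, 100))
  # targeted proportion equal to genome proportion gives log2FC 0
  fams2 <- setNames(rep(c("A", "B"), each = 10), sprintf("t%02d", 1:20))
  res2 <- tfFamilyEnrichment(sprintf("t%02d", c(1:3, 11:13)), fams2)
  expect_equal(res2$log2fc, c(0, 0))
  # log2FC sign agrees with the hypergeometric tail direction
  set.seed(83)
  for (i in 1:20) {
    fam <- setNames(sample(c("F1", "F2", "F3"), 60, TRUE),
                    sprintf("x%02d", 1:60))
    tg <- sample(names(fam), 20)
    r <- tfFamilyEnrichment(tg, fam, minFamilySize = 1)
    for (j in seq_len(nrow(r))) {
      pOver <- hypergeomTest(r$targeted_in_family[j], 20,
                             r$family_size[j], 60, tail = "over")
      pUnder <- hypergeomTest(r$targeted_in_family[j], 20,
                              r$family_size[j], 60, tail = "under")
      if (r$log2fc[j] > 0) expect_lte(pOver, pUnder)
      if (r$log2fc[j] < 0) expect_lte(pUnder, pOver)
    }
  }
})

test_that("flanking-gene categories follow the promoter rules", {
  genes <- GRanges("chr1", IRanges(c(10000, 30000, 50000, 70000),
                                   width = 2000), strand = "+")
  genes$gene_id <- c("G1", "G2", "G3", "G4")
  genes$tss <- start(genes)
  hel <- GRanges("chr1", IRanges(c(10000 - 2000,   # G1: -2 kb
                                   30000 - 2000,   # G2: -2 kb
                                   50000 - 3500,   # G3: wholly < -3 kb
                                   70000 - 1000),  # G4: -1 kb, no motif
                                 width = 300))
  mm <- GRanges("chr1", IRanges(c(10000 - 1900, 30000 - 1900), width = 10))
  bound <- GRanges("chr1", IRanges(10000 - 1950, width = 200))  # G1 only
  cats <- categorizeFlankingGenes(genes, hel, mm, bound)
  expect_equal(unname(cats["G1"]), "helitron_motif_bound")
  expect_equal(unname(cats["G2"]), "helitron_motif_unbound")
  expect_equal(unname(cats["G3"]), "no_helitron")  # TE outside promoter
  expect_equal(unname(cats["G4"]), "helitron_no_motif")
})

test_that("category counts match a brute-force per-gene scan", {
  set.seed(89)
  genes <- GRanges("chr1", IRanges(seq(5000, 95000, by = 6000),
                                   width = 1500), strand = "+")
  genes$gene_id <- sprintf("G%02d", seq_along(genes))
  genes$tss <- start(genes)
  hel <- randomIntervalSet(40, chroms = "chr1", span = 95000, maxLen = 400)
  mm <- randomIntervalSet(60, chroms = "chr1", span = 95000, maxLen = 10)
  bnd <- randomIntervalSet(20, chroms = "chr1", span = 95000, maxLen = 250)
  cats <- categorizeFlankingGenes(genes, hel, mm, bnd)
  for (i in seq_along(genes)) {
    ps <- max(1, start(genes)[i] - 3000); pe <- start(genes)[i] - 1
    ovl <- function(gr) any(start(gr) <= pe & end(gr) >= ps)
    exp <- if (!ovl(hel)) "no_helitron"
           else if (!ovl(mm)) "helitron_no_motif"
           else if (ovl(bnd)) "helitron_motif_bound"
           else "helitron_motif_unbound"
    expect_equal(unname(cats[genes$gene_id[i]]), exp,
                 label = genes$gene_id[i])
  }
})

test_that("Mann-Whitney comparison is exact for small groups", {
  r <- compareGroupsMW(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                    # 2 of 20 orderings as extreme
  expect_equal(r$U, 0)
  ident <- compareGroupsMW(1:6, 1:6)
  expect_equal(ident$U, 18)                 # n^2/2 midpoint
  expect_equal(ident$p, 1)
  expect_error(compareGroupsMW(numeric(), 1:3), "non-empty")
  set.seed(97)
  for (i in 1:20) {
    x <- sample(1:10, sample(3:8, 1), replace = TRUE)   # ties included
    y <- sample(1:10, sample(3:8, 1), replace = TRUE)
    expect_equal(compareGroupsMW(x, y)$p, oracleMWP(x, y),
                 label = paste("case", i))
  }
  # large samples: tie-corrected continuity-corrected normal approximation
  x <- rnorm(40); y <- rnorm(45, 0.3)
  expect_equal(compareGroupsMW(x, y)$p,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))$p.value)
})

test_that("Mann-Whitney keeps its nominal size under the null", {
  set.seed(101)
  rej <- mean(replicate(400, {
    compareGroupsMW(rnorm(25), rnorm(25))$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("k-means recovers planted structure deterministically", {
  set.seed(103)
  cloud1 <- matrix(rnorm(100, 0), 50, 2)
  cloud2 <- matrix(rnorm(100, 8), 50, 2)
  x <- rbind(cloud1, cloud2)
  fit <- kmeansCluster(x, 2, seed = 5)
  truth <- rep(1:2, each = 50)
  expect_equal(adjustedRandIndex(fit$labels, truth), 1)
  # duplicated rows get identical labels
  fit2 <- kmeansCluster(rbind(x, x[1:5, ]), 2, seed = 5)
  expect_equal(fit2$labels[101:105], fit2$labels[1:5])
  # determinism and restart optimality
  fit3 <- kmeansCluster(x, 2, seed = 5)
  expect_identical(fit$labels, fit3$labels)
  single <- kmeansCluster(x, 2, seed = 5, nInit = 1)
  expect_lte(fit$withinss, single$withinss)
  expect_error(kmeansCluster(x[1:3, ], 5), "more clusters")

  # three planted expression-trend archetypes (down, mild-up, mild-down)
  trends <- list(c(0, -1, -2, -3), c(0, 0.4, 0.8, 1.0), c(0, -0.3, -0.5, -0.6))
  m <- do.call(rbind, lapply(1:3, function(k)
    matrix(rep(trends[[k]], each = 60), 60, 4) + rnorm(240, 0, 0.15)))
  fit4 <- kmeansCluster(m, 3, seed = 7)
  expect_gte(adjustedRandIndex(fit4$labels, rep(1:3, each = 60)), 0.9)
})
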