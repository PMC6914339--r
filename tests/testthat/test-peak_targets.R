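test_that("commonPeaks emits merged pairwise intersections", {
  r1 <- GRanges("chr1", IRanges(101, 300))   # BED [100,300)
  r2 <- GRanges("chr1", IRanges(201, 400))   # BED [200,400)
  bss <- commonPeaks(r1, r2)
  expect_s4_class(bss, "BindingSiteSet")
  expect_equal(start(sites(bss)), 201L)
  expect_equal(end(sites(bss)), 300L)
  expect_equal(unname(reproducibility(bss)), c(1, 1))

  disj <- commonPeaks(GRanges("chr1", IRanges(1, 50)),
                      GRanges("chr1", IRanges(100, 150)))
  expect_equal(length(disj), 0L)
  expect_equal(unname(reproducibility(disj)), c(0, 0))
  expect_error(commonPeaks(GRanges(), r2), "non-empty")

  # one rep1 peak spanning two rep2 peaks gives two sites
  span <- GRanges("chr1", IRanges(1, 1000))
  two <- GRanges("chr1", IRanges(c(100, 500), c(200, 600)))
  got <- sites(commonPeaks(span, two))
  expect_equal(start(got), c(100L, 500L))
  expect_equal(end(got), c(200L, 600L))
})

test_that("commonPeaks agrees with the quadratic pairing oracle", {
  set.seed(19)
  for (rep in 1:3) {
    r1 <- randomIntervalSet(60, chroms = "chr1")
    r2 <- randomIntervalSet(60, chroms = "chr1")
    got <- sites(commonPeaks(r1, r2))
    prs <- oracleIntersect(r1, r2)
    inter <- GRanges("chr1",
                     IRanges(pmax(start(r1)[prs$queryHits],
                                  start(r2)[prs$subjectHits]),
                             pmin(end(r1)[prs$queryHits],
                                  end(r2)[prs$subjectHits])))
    exp <- reduce(inter, min.gapwidth = 0L)
    expect_identical(granges(got), exp)
  }
  # idempotence: commonPeaks(a, a) returns a (up to merging)
  a <- reduce(randomIntervalSet(40, chroms = "chr1"), min.gapwidth = 0L)
  expect_identical(granges(sites(commonPeaks(a, a))), a)
})

test_that("annotation distances are orientation-aware and minimal", {
  genes <- GRanges("chr1", IRanges(c(1000, 5000), c(1999, 5999)),
                   strand = c("+", "-"))
  genes$gene_id <- c("Gplus", "Gminus")
  genes$tss <- c(1000L, 5999L)
  # midpoint 250 bp 5' of the + TSS
  s1 <- GRanges("chr1", IRanges(700, 800))       # midpoint 750
  a1 <- annotateSites(s1, genes)
  expect_equal(a1$gene_id, "Gplus")
  expect_equal(a1$distance, -250)
  expect_equal(a1$feature, "promoter")
  # minus-strand gene: 250 bp genomically downstream of its TSS is upstream
  s2 <- GRanges("chr1", IRanges(6199, 6299))     # midpoint 6249
  a2 <- annotateSites(s2, genes)
  expect_equal(a2$gene_id, "Gminus")
  expect_equal(a2$distance, -250)
  expect_equal(a2$feature, "promoter")
  # midpoint inside the gene body
  s3 <- GRanges("chr1", IRanges(1400, 1500))
  expect_equal(annotateSites(s3, genes)$feature, "gene_body")
})

test_that("mean |distance| matches the exhaustive nearest-gene oracle", {
  set.seed(23)
  genes <- GRanges("chr1", IRanges(seq(2000, 98000, by = 4000), width = 1500),
                   strand = sample(c("+", "-"), 25, replace = TRUE))
  genes$gene_id <- sprintf("G%02d", seq_along(genes))
  genes$tss <- ifelse(as.character(strand(genes)) == "-",
                      end(genes), start(genes))
  st <- sample.int(95000, 100)
  sitesGr <- GRanges("chr1", IRanges(st, width = 200))
  ann <- annotateSites(sitesGr, genes)
  mids <- floor((start(sitesGr) + end(sitesGr)) / 2)
  oracleDist <- vapply(mids, function(m) {
    d <- ifelse(as.character(strand(genes)) == "-", genes$tss - m,
                m - genes$tss)
    d[which.min(abs(d))]
  }, 0)
  expect_equal(mean(abs(ann$distance)), mean(abs(oracleDist)))
})

test_that("target calling honours the inclusive window and is monotone", {
  ann <- data.frame(gene_id = c("A", "B", "C", "C"),
                    distance = c(-200, 501, -100, 300))
  expect_equal(callTargets(ann), c("A", "C"))        # B at +501 excluded
  expect_equal(callTargets(ann, downstream = 501), c("A", "B", "C"))
  expect_error(callTargets(ann, upstream = -1), "upstream")
  # widening the window never removes targets
  set.seed(5)
  rand <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     distance = round(runif(200, -4000, 4000)))
  t1 <- callTargets(rand, 1500, 500)
  t2 <- callTargets(rand, 3000, 1000)
  expect_true(all(t1 %in% t2))
})
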