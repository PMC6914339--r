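test_that("local alignment reproduces closed-form scores", {
  a <- "ACGTACGTACGT"
  aln <- localAlign(a, a)
  expect_equal(aln$score, 24)          # 12 matches x 2
  expect_equal(aln$identity, 100)
  expect_equal(aln$length, 12)

  # 21-mers differing at the centre base: 20 matches and one mismatch
  # beats any gapped variant: 2*20 - 3 = 37
  b1 <- paste0(strrep("AC", 5), "G", strrep("TG", 5))
  b2 <- paste0(strrep("AC", 5), "C", strrep("TG", 5))
  aln2 <- localAlign(b1, b2)
  expect_equal(aln2$score, 37)
  expect_equal(aln2$length, 21)
  expect_error(localAlign("", "ACGT"), "non-empty")
})

test_that("alignment scores equal the naive affine DP oracle", {
  set.seed(67)
  for (i in 1:12) {
    a <- randomDnaString(sample(20:60, 1))
    b <- randomDnaString(sample(20:60, 1))
    expect_equal(localAlign(a, b)$score, oracleLocalAlignScore(a, b),
                 label = paste("pair", i))
    expect_equal(localAlign(a, b)$score, localAlign(b, a)$score)
  }
})

test_that("homology thresholds are strict at their boundaries", {
  mkAln <- function(len, identity, startA = 1, endA = NULL) {
    if (is.null(endA)) endA <- startA + len - 1
    structure(list(score = 50, length = len, identity = identity,
                   startA = startA, endA = endA, startB = 1,
                   endB = len, alignedA = "", alignedB = ""),
              class = "LocalAlignment")
  }
  motifSpan <- c(50, 59)
  # passing case: > 30 columns, > 70% identity, motif fully covered
  expect_true(as.logical(
    pairHomology(mkAln(40, 75, 40, 79), motifSpan)))
  # alignment length exactly 30 is rejected ("longer than 30 bp")
  expect_false(as.logical(
    pairHomology(mkAln(30, 75, 40, 69), motifSpan)))
  # identity exactly 70.0 is rejected ("more than 70%")
  expect_false(as.logical(
    pairHomology(mkAln(40, 70, 40, 79), motifSpan)))
  # motif coverage 8 of 10 is rejected (needs >= 9)
  expect_false(as.logical(
    pairHomology(mkAln(40, 75, 52, 91), motifSpan)))
  # coverage exactly 9 passes
  expect_true(as.logical(
    pairHomology(mkAln(40, 75, 51, 90), motifSpan)))
  expect_error(pairHomology(mkAln(40, 75), NULL), "motifSpan")

  # cross-species profile: span > 100 nt and identity > 60
  expect_true(as.logical(
    pairHomology(mkAln(101, 61, 1, 101), profile = "cross_species")))
  expect_false(as.logical(
    pairHomology(mkAln(100, 61, 1, 100), profile = "cross_species")))
  expect_false(as.logical(
    pairHomology(mkAln(101, 60, 1, 101), profile = "cross_species")))
})

test_that("cluster merging equals transitive closure", {
  cl <- clusterPairs(c("A", "B", "C"),
                     data.frame(x = c("A", "B"), y = c("B", "C")))
  expect_equal(unique(cl$cluster), "A")
  cl2 <- clusterPairs(c("A", "B", "C"), NULL)
  expect_equal(cl2$cluster, c("A", "B", "C"))
  expect_error(clusterPairs(c("A"), data.frame(x = "A", y = "Z")),
               "unknown")
  set.seed(71)
  els <- sprintf("n%02d", 1:50)
  prs <- data.frame(a = sample(els, 40, TRUE), b = sample(els, 40, TRUE))
  got <- clusterPairs(els, prs)
  lab <- oracleComponents(els, as.matrix(prs))
  # identical partitions (compare co-membership)
  gmap <- setNames(got$cluster, got$element)
  for (i in 1:49) for (j in (i + 1):50) {
    expect_equal(gmap[[els[i]]] == gmap[[els[j]]],
                 lab[[els[i]]] == lab[[els[j]]])
  }
})

test_that("a mutated TE family clusters together, unrelated stay apart", {
  set.seed(73)
  ancestor <- randomDnaString(300)
  motifStart <- 146
  ancestor <- paste0(substr(ancestor, 1, motifStart - 1), "CCAATTAAGG",
                     substr(ancestor, motifStart + 10, 300))
  fam <- c(ancestor, vapply(1:9, function(i)
    mutateSequence(ancestor, 0.05, motifStart, motifStart + 9), ""))
  unrel <- vapply(1:6, function(i) randomDnaString(300), "")
  seqs <- c(fam, unrel)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  spans <- rep(list(c(motifStart, motifStart + 9)), length(seqs))
  names(spans) <- names(seqs)
  hc <- homologyClusters(seqs, spans)
  tab <- table(hc$clusters$cluster)
  expect_equal(sort(as.vector(tab), decreasing = TRUE),
               c(10, rep(1, 6)))
  famCl <- hc$clusters$cluster[hc$clusters$element == "s01"]
  expect_setequal(hc$clusters$element[hc$clusters$cluster == famCl],
                  sprintf("s%02d", 1:10))
})
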