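smallConfig <- function(seed = 3, ...) {
  simulationConfig(seed = seed, n_chrom = 1, chrom_length = 5e5,
                   n_genes = 30,
                   te_counts = c("RC/Helitron" = 24, "LTR/Gypsy" = 14,
                                 "DNA/MuDR" = 12),
                   peak_count = 30, n_expressed_genes = 25, ...)
}

test_that("one seed yields byte-identical synthetic bundles", {
  cfg <- smallConfig()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateAll(cfg, d1)
  simulateAll(cfg, d2)
  for (f in list.files(d1)) {
    if (grepl("png$", f)) next
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("planted motif carriers match the configured fraction exactly", {
  cfg <- smallConfig()
  ann <- simulateAnnotation(cfg)
  expect_equal(sum(ann$tes$motif_carrier), round(0.5 * 24))
  expect_true(all(ann$tes$superfamily[ann$tes$motif_carrier] ==
                    "RC/Helitron"))
  # scanning the genome recovers exactly the carriers
  perf <- scanConsensus(ann$genome, nearlyPerfect = FALSE)
  carr <- ann$tes[ann$tes$motif_carrier]
  other <- ann$tes[!ann$tes$motif_carrier]
  expect_true(all(countOverlaps(carr, perf, ignore.strand = TRUE) > 0))
  expect_equal(sum(countOverlaps(other, perf, ignore.strand = TRUE) > 0), 0)

  cfg0 <- smallConfig(helitron_motif_fraction = 0)
  ann0 <- simulateAnnotation(cfg0)
  perf0 <- scanConsensus(ann0$genome, nearlyPerfect = FALSE)
  hel0 <- ann0$tes[ann0$tes$superfamily == "RC/Helitron"]
  expect_equal(sum(countOverlaps(hel0, perf0, ignore.strand = TRUE) > 0), 0)
})

test_that("replicate structure follows jitter and specific-peak settings", {
  cfg <- smallConfig(replicate_jitter = 0, replicate_specific_fraction = 0)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(ann, cfg)
  expect_equal(length(pk$rep1), cfg$peak_count)
  # with no jitter and no private peaks the replicates agree exactly
  expect_equal(sort(start(pk$rep1)), sort(start(pk$rep2)))

  cfg5 <- smallConfig(replicate_specific_fraction = 0.5)
  pk5 <- simulatePeaks(simulateAnnotation(cfg5), cfg5)
  expect_equal(nrow(pk5$truthPeaks), round(0.5 * cfg5$peak_count))
})

test_that("full targeting places every truth peak on a promoter carrier", {
  cfg <- smallConfig(peak_motif_targeting = 1,
                     replicate_specific_fraction = 0)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(ann, cfg)
  expect_true(all(pk$truthPeaks$on_carrier))
  carr <- ann$tes[ann$tes$motif_carrier]
  prom <- promoterUniverse(ann$genes)
  hostGenes <- unique(prom$gene_id[subjectHits(
    findOverlaps(carr, prom, ignore.strand = TRUE))])
  expect_true(all(pk$truthPeaks$gene_id %in% hostGenes))
})

test_that("allelic counts respect conservation and the generating law", {
  cfg <- smallConfig(deterministic_counts = TRUE)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(ann, cfg)
  al <- simulateAllelicData(ann, pk, cfg)
  cnt <- al$counts
  expect_true(all(cnt$maternal >= 0 & cnt$paternal >= 0))
  truth <- al$truthImprinting
  bi2 <- cnt[cnt$cross == "2x" &
               cnt$gene_id %in% truth$gene_id[truth$label == "biallelic"], ]
  frac <- bi2$maternal / (bi2$maternal + bi2$paternal)
  expect_true(all(abs(frac - 2 / 3) < 0.01))   # rounding error only
  # planted MEGs clear the threshold in every replicate at zero noise
  meg2 <- cnt[cnt$cross == "2x" &
                cnt$gene_id %in% truth$gene_id[truth$label == "MEG"], ]
  mfrac <- meg2$maternal / (meg2$maternal + meg2$paternal)
  expect_true(all(mfrac >= 8 / 9))

  # per-bin allele tracks sum to the emitted total track
  tr <- al$tracks
  expect_equal(tr$h3k27me3_maternal$score + tr$h3k27me3_paternal$score,
               tr$h3k27me3_total$score, tolerance = 1e-12)
  expect_identical(granges(tr$h3k27me3_maternal),
                   granges(tr$h3k27me3_total))
})
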