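#' Run the full analysis pipeline
#'
#' Orchestrates every stage over one configuration: (optionally) simulate
#' a synthetic dataset, define replicate-supported binding sites, annotate
#' them and call target genes, scan motifs and compute densities, run the
#' TE-overlap permutation test, cluster motif-carrying TE sequences by
#' homology, categorize TE-flanked genes, profile allele-specific
#' chromatin signal, and classify imprinting. Every stage writes its
#' TSV/BED outputs into `outDir`, a manifest records parameters, seed and
#' stage outputs, and — when planted truth is available — a recovery
#' report scores the pipeline against it (target recall/precision,
#' homology-cluster and archetype recovery, imprinting accuracy,
#' permutation p for the planted Helitron enrichment).
#'
#' The master seed fans out to fixed per-stage child seeds so stages are
#' individually reproducible.
#'
#' @param config A [simulationConfig()] for synthetic runs, or a list
#'   with file paths (`genes`, `tes`, `rep1`, `rep2`, `counts`, optional
#'   tracks) for user data.
#' @param outDir Output directory.
#' @param nPermutations Iterations for the TE-overlap permutation test
#'   (default 1000 for pipeline runs; the study scale is 10000).
#' @param maxHomologySeqs Cap on motif-carrying TE sequences entering
#'   all-pairs alignment (default 60).
#' @return Invisibly, a list with each stage's in-memory result, the
#'   manifest, and (synthetic runs) the recovery report.
#' @export
runPipeline <- function(config, outDir, nPermutations = 1000,
                        maxHomologySeqs = 60) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  failedMarker <- file.path(outDir, "FAILED")
  if (file.exists(failedMarker)) unlink(failedMarker)
  runStage <- function(name, expr) {
    stages[[length(stages) + 1L]] <<- name
    tryCatch(expr, error = function(e) {
      writeLines(paste("failed at stage:", name, "-",
                       conditionMessage(e)), failedMarker)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  synthetic <- inherits(config, "SimulationConfig")
  bundle <- runStage("simulate", {
    if (synthetic) simulateAll(config, file.path(outDir, "synthetic"))
    else loadUserBundle(config)
  })
  ann <- bundle$annotation
  cfg <- if (synthetic) config else NULL
  seed <- if (synthetic) config$seed else 1L

  bss <- runStage("common_peaks",
                  commonPeaks(bundle$peaks$rep1, bundle$peaks$rep2))
  annDf <- runStage("annotate_targets", {
    a <- annotateSites(bss, ann$genes)
    writeTsv(a, file.path(outDir, "site_annotation.tsv"))
    a
  })
  targets <- runStage("call_targets", {
    t <- callTargets(annDf)
    writeTsv(data.frame(gene_id = t), file.path(outDir, "targets.tsv"))
    t
  })

  motifRes <- runStage("motif_scan", {
    mm <- scanConsensus(ann$genome)
    writeBed(mm, file.path(outDir, "motif_matches.bed"),
             feature = paste(mm$class, mm$matched, sep = "|"))
    regions <- split(granges(ann$tes), ann$tes$superfamily)
    dens <- motifDensity(as.list(regions), mm)
    writeTsv(dens$density, file.path(outDir, "motif_density.tsv"))
    if (!is.null(dens$tests))
      writeTsv(dens$tests, file.path(outDir, "motif_density_tests.tsv"))
    list(matches = mm, density = dens)
  })

  permRes <- runStage("te_overlap", {
    prom <- promoterUniverse(ann$genes)
    teBy <- as.list(split(granges(ann$tes), ann$tes$superfamily))
    pr <- permutationTest(bss, teBy, prom, nIter = nPermutations,
                          seed = seed + 10L)
    writeTsv(pr, file.path(outDir, "te_overlap_permutation.tsv"))
    pr
  })

  homRes <- runStage("homology_clusters", {
    carriers <- ann$tes[ann$tes$motif_carrier]
    if (length(carriers) > maxHomologySeqs)
      carriers <- carriers[seq_len(maxHomologySeqs)]
    if (length(carriers) >= 2L) {
      seqs <- DNAStringSet(lapply(seq_along(carriers), function(i) {
        ch <- as.character(seqnames(carriers))[i]
        Biostrings::subseq(ann$genome[[ch]], start(carriers)[i],
                           end(carriers)[i])
      }))
      names(seqs) <- carriers$te_id
      spans <- lapply(seq_along(carriers), function(i) {
        s <- carriers$motif_start[i] - start(carriers)[i] + 1L
        c(s, s + 9L)
      })
      names(spans) <- carriers$te_id
      hc <- homologyClusters(seqs, spans)
      writeTsv(hc$pairs, file.path(outDir, "homology_pairs.tsv"))
      writeTsv(hc$clusters, file.path(outDir, "homology_clusters.tsv"))
      hc
    } else NULL
  })

  catRes <- runStage("flanking_categories", {
    hel <- ann$tes[ann$tes$superfamily == "RC/Helitron"]
    cats <- categorizeFlankingGenes(ann$genes, hel, motifRes$matches, bss)
    writeTsv(data.frame(gene_id = names(cats), category = unname(cats)),
             file.path(outDir, "flanking_categories.tsv"))
    cats
  })

  profRes <- runStage("allelic_profiles", {
    if (is.null(bundle$allelic)) return(NULL)
    tr <- bundle$allelic$tracks
    sw <- bundle$allelic$siteWindows
    mats <- list(maternal = binSignal(tr$h3k27me3_maternal, sw),
                 paternal = binSignal(tr$h3k27me3_paternal, sw),
                 total = binSignal(tr$h3k27me3_total, sw))
    cl <- clusterSites(mats$total, k = 2, seed = seed + 20L)
    writeTsv(data.frame(site = names(cl$labels), cluster = cl$labels),
             file.path(outDir, "signal_clusters.tsv"))
    mg <- data.frame(bin = as.integer(colnames(mats$total)),
                     maternal = metagene(mats$maternal),
                     paternal = metagene(mats$paternal),
                     total = metagene(mats$total))
    writeTsv(mg, file.path(outDir, "metagene.tsv"))
    plotMetagene(mg, file.path(outDir, "metagene.png"))
    methMats <- list(maternal = binSignal(tr$meth_maternal, sw),
                     paternal = binSignal(tr$meth_paternal, sw))
    groups <- bundle$allelic$truthSites$group
    keepRows <- rownames(methMats$maternal)
    groups <- groups[match(keepRows, bundle$allelic$truthSites$site_id)]
    meth <- methylationContrast(methMats, groups)
    writeTsv(meth$siteMeans, file.path(outDir, "meth_site_means.tsv"))
    list(mats = mats, clusters = cl, metagene = mg, meth = meth)
  })

  imprintRes <- runStage("imprinting", {
    if (is.null(bundle$allelic)) return(NULL)
    pr <- parentalRatio(bundle$allelic$counts)
    calls <- classifyImprinting(pr)
    writeTsv(calls, file.path(outDir, "imprinting_calls.tsv"))
    ct <- attr(calls, "crossTable")
    if (!is.null(ct))
      writeTsv(as.data.frame(ct),
               file.path(outDir, "imprinting_cross_table.tsv"))
    calls
  })

  recovery <- NULL
  if (synthetic) {
    recovery <- runStage("recovery_report",
                         recoveryReport(bundle, bss, targets, permRes,
                                        homRes, profRes, imprintRes))
    writeTsv(recovery, file.path(outDir, "recovery_report.tsv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("imprintTE")),
    seed = seed, synthetic = synthetic, stages = stages,
    n_permutations = nPermutations,
    outputs = sort(list.files(outDir, recursive = TRUE)))
  if (synthetic) {
    cfgOut <- unclass(config)
    cfgOut$te_counts <- as.list(cfgOut$te_counts)
    manifest$parameters <- cfgOut
  }
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(bindingSites = bss, annotation = annDf,
                 targets = targets, motifs = motifRes, permutation = permRes,
                 homology = homRes, categories = catRes,
                 profiles = profRes, imprinting = imprintRes,
                 recovery = recovery, manifest = manifest))
}

loadUserBundle <- function(paths) {
  need <- c("genes", "rep1", "rep2")
  missing <- need[!vapply(need, function(n)
    !is.null(paths[[n]]) && file.exists(paths[[n]]), TRUE)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ann <- list(genes = readGenes(paths$genes),
              genome = if (!is.null(paths$genome))
                readDNAStringSet(paths$genome) else NULL,
              tes = if (!is.null(paths$tes)) {
                te <- parseIntervals(paths$tes, "bed")
                te$superfamily <- te$name
                te$motif_carrier <- FALSE
                te
              } else GRanges())
  list(annotation = ann,
       peaks = list(rep1 = parseIntervals(paths$rep1, "bed"),
                    rep2 = parseIntervals(paths$rep2, "bed")),
       allelic = if (!is.null(paths$counts)) {
         list(counts = read.table(paths$counts, header = TRUE,
                                  sep = "\t"),
              tracks = NULL, siteWindows = NULL, truthSites = NULL)
       } else NULL)
}

# score the pipeline against the generator's planted truth
recoveryReport <- function(bundle, bss, targets, permRes, homRes,
                           profRes, imprintRes) {
  truthPeaks <- bundle$peaks$truthPeaks
  truthTargets <- unique(truthPeaks$gene_id[
    truthPeaks$tss_offset >= -1500 & truthPeaks$tss_offset <= 500])
  recall <- mean(truthTargets %in% targets)
  falseRate <- if (length(targets))
    mean(!(targets %in% truthPeaks$gene_id)) else 0
  rows <- list(data.frame(metric = "target_recall", value = recall),
               data.frame(metric = "target_false_rate", value = falseRate))

  hel <- permRes[permRes$feature == "RC/Helitron", , drop = FALSE]
  if (nrow(hel)) {
    rows <- c(rows,
              list(data.frame(metric = "helitron_overlap_p",
                              value = hel$p),
                   data.frame(metric = "helitron_overlap_z",
                              value = hel$z)))
  }
  if (!is.null(homRes)) {
    tab <- table(homRes$clusters$cluster)
    rows <- c(rows, list(
      data.frame(metric = "homology_largest_cluster_fraction",
                 value = max(tab) / sum(tab))))
  }
  if (!is.null(profRes)) {
    truthSites <- bundle$allelic$truthSites
    lab <- profRes$clusters$labels
    truthArch <- truthSites$archetype[match(names(lab),
                                            truthSites$site_id)]
    rows <- c(rows, list(
      data.frame(metric = "signal_cluster_ari",
                 value = adjustedRandIndex(
                   lab, as.integer(factor(truthArch))))))
  }
  if (!is.null(imprintRes)) {
    truthImp <- bundle$allelic$truthImprinting
    m <- merge(imprintRes, truthImp, by = "gene_id")
    m <- m[m$label != "insufficient_data", , drop = FALSE]
    rows <- c(rows, list(
      data.frame(metric = "imprinting_accuracy",
                 value = mean(m$label.x == m$label.y))))
  }
  do.call(rbind, rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and reference labels;
#' 1 means identical partitions, 0 the expectation under independence.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxidx <- (sumA + sumB) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

#' Plot a maternal/paternal/total metagene profile
#'
#' @param mg `data.frame` with `bin`, `maternal`, `paternal`, `total`.
#' @param path PNG output path.
#' @return Invisibly, the path.
#' @export
plotMetagene <- function(mg, path) {
  png(path, width = 800, height = 500)
  on.exit(dev.off())
  plot(mg$bin, mg$total, type = "l", lwd = 2, col = "grey30",
       xlab = "position relative to site centre (bp)",
       ylab = "mean signal", ylim = range(mg[, -1], na.rm = TRUE))
  lines(mg$bin, mg$maternal, lwd = 2, col = "deeppink3")
  lines(mg$bin, mg$paternal, lwd = 2, col = "steelblue3")
  legend("topright", legend = c("total", "maternal", "paternal"),
         col = c("grey30", "deeppink3", "steelblue3"), lwd = 2, bty = "n")
  invisible(path)
}
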