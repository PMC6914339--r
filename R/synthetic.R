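#' Configuration of the synthetic dataset generator
#'
#' Bundles every parameter of the planted-truth simulator: a genome with
#' genes and TE copies of several superfamilies, a subset of RC/Helitron
#' copies carrying a planted 10-bp CArG-box motif descended from one
#' ancestral element, two-replicate ChIP peaks enriched at motif-bearing
#' promoter TEs, beta-binomially dispersed maternal/paternal read counts
#' with planted MEG/PEG labels under the 2x (2 maternal : 3 total) and
#' 3x-paternal-excess (2 maternal : 4 total) expectations, and two
#' H3K27me3 profile archetypes (flank-enriched with a depleted centre
#' versus flat-depleted).
#'
#' @param seed Integer master seed; one seed fixes every emitted byte.
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes,gene_length Gene count and length range (bases).
#' @param promoter_length Promoter span upstream of the TSS (default 3000).
#' @param te_counts Named integer vector of TE copies per superfamily;
#'   must contain `"RC/Helitron"`.
#' @param te_length TE length range for non-carrier copies.
#' @param te_promoter_fraction Fraction of TE copies placed inside gene
#'   promoters (the rest are intergenic).
#' @param helitron_motif_fraction Fraction of RC/Helitron copies carrying
#'   the planted perfect motif.
#' @param ancestor_length Length of the ancestral motif-carrying element.
#' @param substitution_rate Per-base substitution rate applied to each
#'   descendant of the ancestral element (motif bases preserved).
#' @param motif_consensus Planted motif consensus (default the CArG-box).
#' @param peak_count,peak_length Peak number and length range.
#' @param peak_motif_targeting Fraction of peaks centred on motif-bearing
#'   promoter TEs; the remainder fall uniformly in promoter space.
#' @param replicate_jitter Replicate-2 peaks are replicate-1 peaks shifted
#'   by up to this many bases either way.
#' @param replicate_specific_fraction Fraction of each replicate's peaks
#'   that the other replicate lacks.
#' @param n_expressed_genes Genes with allele-specific counts.
#' @param meg_fraction,peg_fraction Fractions of expressed genes planted
#'   as MEGs / PEGs (the rest are biallelic).
#' @param allelic_dispersion Beta-binomial overdispersion rho in \[0, 1);
#'   0 gives plain binomial sampling.
#' @param deterministic_counts When TRUE, maternal counts are the rounded
#'   expectation (the exactly noise-free limit used for 100%-recovery
#'   checks).
#' @param depth_range Per-replicate total read depth range.
#' @param label_margin Planted MEGs/PEGs sit at `label_margin` times the
#'   four-fold classification threshold, measured on the log-odds scale
#'   where the fold-deviation is defined (default 1.5, i.e. expected
#'   odds of `4^1.5` times the biallelic expectation; 1 plants exactly
#'   at the threshold).
#' @param cluster1_fraction Fraction of binding sites with the
#'   flank-enriched/centre-depleted maternal H3K27me3 archetype.
#' @param flank_amplitude,center_depletion_width,signal_baseline,
#'   signal_noise_sd Signal archetype parameters.
#' @param signal_window,signal_bin Window and bin size for emitted tracks.
#' @param meth_baseline,meth_meg_paternal_offset,meth_noise_sd CG
#'   methylation track parameters (paternal alleles of MEG-associated
#'   sites get the offset).
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chrom = 1L,
                             chrom_length = 3e6,
                             n_genes = 200L,
                             gene_length = c(1000, 3000),
                             promoter_length = 3000,
                             te_counts = c("RC/Helitron" = 120L,
                                           "LTR/Gypsy" = 90L,
                                           "DNA/MuDR" = 90L),
                             te_length = c(150, 600),
                             te_promoter_fraction = 0.5,
                             helitron_motif_fraction = 0.5,
                             ancestor_length = 400L,
                             substitution_rate = 0.05,
                             motif_consensus = "CCWWWWWWGG",
                             peak_count = 150L,
                             peak_length = c(150, 400),
                             peak_motif_targeting = 0.7,
                             replicate_jitter = 25L,
                             replicate_specific_fraction = 0.1,
                             n_expressed_genes = 150L,
                             meg_fraction = 0.15,
                             peg_fraction = 0.15,
                             allelic_dispersion = 0.02,
                             deterministic_counts = FALSE,
                             depth_range = c(200, 400),
                             label_margin = 1.5,
                             cluster1_fraction = 0.5,
                             flank_amplitude = 2,
                             center_depletion_width = 500,
                             signal_baseline = 0.2,
                             signal_noise_sd = 1,
                             signal_window = 2000L,
                             signal_bin = 50L,
                             meth_baseline = 0.3,
                             meth_meg_paternal_offset = 0.3,
                             meth_noise_sd = 0.02) {
  cfg <- as.list(environment())
  fracs <- c("te_promoter_fraction", "helitron_motif_fraction",
             "peak_motif_targeting", "replicate_specific_fraction",
             "meg_fraction", "peg_fraction", "cluster1_fraction")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must lie in [0, 1]", call. = FALSE)
  if (cfg$meg_fraction + cfg$peg_fraction > 1)
    stop("meg_fraction + peg_fraction must not exceed 1", call. = FALSE)
  if (cfg$allelic_dispersion < 0 || cfg$allelic_dispersion >= 1)
    stop("allelic_dispersion must lie in [0, 1)", call. = FALSE)
  if (!"RC/Helitron" %in% names(cfg$te_counts))
    stop("te_counts must contain an 'RC/Helitron' entry", call. = FALSE)
  if (cfg$signal_window %% cfg$signal_bin != 0)
    stop("signal_window must be divisible by signal_bin", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  genome: %d chrom x %g bp; %d genes; TEs: %s\n",
              x$n_chrom, x$chrom_length, x$n_genes,
              paste(names(x$te_counts), x$te_counts, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  peaks: %d (targeting %.0f%%); expressed genes: %d\n",
              x$peak_count, 100 * x$peak_motif_targeting,
              x$n_expressed_genes))
  invisible(x)
}

randomDna <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)],
        collapse = "")
}

# one realization of the consensus (IUPAC codes resolved at random)
realizeConsensus <- function(consensus) {
  sets <- iupacSets()
  paste(vapply(strsplit(consensus, "")[[1L]], function(cd) {
    s <- sets[[cd]]
    s[sample.int(length(s), 1L)]
  }, ""), collapse = "")
}

#' Simulate the genome annotation with planted motif-carrying TEs
#'
#' Generates a uniform-composition genome, non-overlapping gene models
#' with clear promoter space, and TE copies of the configured
#' superfamilies. Exactly `round(helitron_motif_fraction * n_helitrons)`
#' RC/Helitron copies carry a planted perfect motif; all carriers are
#' sequence-mutated descendants of one ancestral element, so downstream
#' homology clustering can recover the family. Chance perfect-motif
#' occurrences inside TE spans or promoters are mutated away so that the
#' planted carrier flags are exact.
#'
#' @param config A [simulationConfig()].
#' @return List with `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id`, `tss`), `tes` (`GRanges` with `te_id`, `superfamily`,
#'   `motif_carrier`, `motif_start`), `truthTe` (data.frame) and `config`.
#' @export
simulateAnnotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, simulateAnnotationImpl(config))
}

simulateAnnotationImpl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genomeChars <- lapply(chroms, function(ch)
    strsplit(randomDna(cfg$chrom_length), "")[[1L]])
  names(genomeChars) <- chroms

  # --- genes: sequential placement with promoter-sized spacing ---
  perChrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  geneRows <- list()
  gi <- 0L
  for (ch in chroms) {
    cursor <- cfg$promoter_length + 1000
    nHere <- min(perChrom, cfg$n_genes - gi)
    for (i in seq_len(nHere)) {
      glen <- round(runif(1, cfg$gene_length[1L], cfg$gene_length[2L]))
      st <- cursor + round(runif(1, 0, 2000))
      en <- st + glen - 1
      if (en > cfg$chrom_length - cfg$promoter_length - 1000)
        stop("genome too small to place the requested genes",
             call. = FALSE)
      gi <- gi + 1L
      geneRows[[gi]] <- data.frame(
        chrom = ch, start = st, end = en,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("GENE%04d", gi))
      cursor <- en + cfg$promoter_length + 1000
    }
  }
  gdf <- do.call(rbind, geneRows)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand)
  genes$gene_id <- gdf$gene_id
  genes$tss <- ifelse(gdf$strand == "-", gdf$end, gdf$start)
  seqlengths(genes) <- setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)

  # --- TE copies ---
  superfam <- rep(names(cfg$te_counts), cfg$te_counts)
  nTe <- length(superfam)
  isHel <- superfam == "RC/Helitron"
  nCarrier <- round(cfg$helitron_motif_fraction * sum(isHel))
  carrier <- logical(nTe)
  if (nCarrier > 0)
    carrier[sample(which(isHel), nCarrier)] <- TRUE

  # ancestral motif-carrying element; descendants are substitution-mutated
  motifInstance <- realizeConsensus(cfg$motif_consensus)
  motifLen <- nchar(motifInstance)
  motifOffset <- floor((cfg$ancestor_length - motifLen) / 2)  # 0-based
  ancestor <- strsplit(randomDna(cfg$ancestor_length), "")[[1L]]
  ancestor[motifOffset + seq_len(motifLen)] <-
    strsplit(motifInstance, "")[[1L]]

  teLen <- round(runif(nTe, cfg$te_length[1L], cfg$te_length[2L]))
  teLen[carrier] <- cfg$ancestor_length
  inProm <- runif(nTe) < cfg$te_promoter_fraction
  inProm[carrier] <- TRUE  # carriers live in promoters so peaks can target

  gstr <- as.character(strand(genes))
  teRows <- vector("list", nTe)
  placedChrom <- character()
  placedStart <- integer()
  placedEnd <- integer()
  # carriers are placed first; every copy avoids previously placed copies
  # so one TE never hides another's planted motif
  for (i in order(!carrier)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 200L)
        stop("genome too small to place the requested TE copies",
             call. = FALSE)
      if (inProm[i]) {
        g <- sample.int(length(genes), 1L)
        tss <- genes$tss[g]
        chrom <- as.character(seqnames(genes))[g]
        if (carrier[i]) {
          # motif centre lands 100-1400 bp upstream of the TSS
          upstream <- round(runif(1, 100 + motifLen, 1400))
          if (gstr[g] == "+") {
            motifStart <- tss - upstream        # genomic start of motif
            teStart <- motifStart - motifOffset
          } else {
            motifEnd <- tss + upstream
            motifStart <- motifEnd - motifLen + 1
            teStart <- motifStart - (teLen[i] - motifOffset - motifLen)
          }
        } else {
          upstream <- round(runif(1, motifLen + 1,
                                  cfg$promoter_length - teLen[i]))
          teStart <- if (gstr[g] == "+") tss - upstream else
            tss + upstream - teLen[i] + 1
          motifStart <- NA_integer_
        }
      } else {
        chrom <- chroms[sample.int(length(chroms), 1L)]
        teStart <- round(runif(1, 1, cfg$chrom_length - teLen[i]))
        cand <- GRanges(chrom, IRanges(teStart, teStart + teLen[i] - 1))
        if (sum(countOverlaps(cand, genes, ignore.strand = TRUE)) > 0L)
          next
        motifStart <- NA_integer_
      }
      teStart <- max(1, min(teStart, cfg$chrom_length - teLen[i]))
      teEnd <- teStart + teLen[i] - 1L
      clash <- placedChrom == chrom & placedStart <= teEnd &
        placedEnd >= teStart
      if (!any(clash)) break
    }
    placedChrom <- c(placedChrom, chrom)
    placedStart <- c(placedStart, teStart)
    placedEnd <- c(placedEnd, teEnd)
    teRows[[i]] <- data.frame(
      chrom = chrom, start = teStart, end = teEnd,
      superfamily = superfam[i], carrier = carrier[i],
      motif_start = if (carrier[i]) motifStart else NA_integer_)
  }
  tdf <- do.call(rbind, teRows)
  tdf$te_id <- sprintf("TE%04d", seq_len(nTe))

  # write carrier sequences (mutated ancestor copies) into the genome
  for (i in which(tdf$carrier)) {
    desc <- ancestor
    mut <- runif(cfg$ancestor_length) < cfg$substitution_rate
    mut[motifOffset + seq_len(motifLen)] <- FALSE  # motif preserved
    if (any(mut)) {
      bases <- c("A", "C", "G", "T")
      desc[mut] <- vapply(desc[mut], function(b)
        sample(setdiff(bases, b), 1L), "")
    }
    span <- tdf$start[i]:tdf$end[i]
    genomeChars[[tdf$chrom[i]]][span] <- desc
  }

  tes <- GRanges(tdf$chrom, IRanges(tdf$start, tdf$end))
  tes$te_id <- tdf$te_id
  tes$superfamily <- tdf$superfamily
  tes$motif_carrier <- tdf$carrier
  tes$motif_start <- tdf$motif_start
  seqlengths(tes) <- setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)

  # scrub chance perfect-motif occurrences inside TEs and promoters so
  # that planted carrier flags are exact
  prom <- promoterUniverse(genes, span = cfg$promoter_length)
  scrub <- reduce(c(granges(tes), granges(prom)), ignore.strand = TRUE)
  planted <- GRanges(tdf$chrom[tdf$carrier],
                     IRanges(tdf$motif_start[tdf$carrier],
                             width = motifLen))
  genome <- DNAStringSet(vapply(genomeChars, paste, "", collapse = ""))
  for (round_ in 1:6) {
    matches <- scanConsensus(genome, motif(cfg$motif_consensus),
                             nearlyPerfect = FALSE)
    stray <- matches[countOverlaps(matches, planted,
                                   type = "equal") == 0L]
    stray <- stray[countOverlaps(stray, scrub, ignore.strand = TRUE) > 0L]
    if (length(stray) == 0L) break
    for (j in seq_along(stray)) {
      ch <- as.character(seqnames(stray))[j]
      pos <- start(stray)[j] + 1L  # second base of the CC dinucleotide
      genomeChars[[ch]][pos] <- "A"
    }
    genome <- DNAStringSet(vapply(genomeChars, paste, "", collapse = ""))
  }
  names(genome) <- chroms

  truthTe <- data.frame(te_id = tdf$te_id, superfamily = tdf$superfamily,
                        chrom = tdf$chrom, start = tdf$start,
                        end = tdf$end, motif_carrier = tdf$carrier,
                        motif_start = tdf$motif_start)
  list(genome = genome, genes = sortIntervals(genes),
       tes = sortIntervals(tes), truthTe = truthTe,
       motifInstance = motifInstance, config = cfg)
}

#' Simulate two-replicate ChIP peaks over the annotation
#'
#' A configurable fraction of peaks is centred on the planted motif of
#' motif-carrying promoter TEs (the biological signal); the remainder fall
#' uniformly within promoters (background). Replicate 2 reproduces the
#' shared peak core shifted by up to `replicate_jitter` bases, and each
#' replicate additionally carries `replicate_specific_fraction` private
#' peaks.
#'
#' @param ann Output of [simulateAnnotation()].
#' @param config The same [simulationConfig()].
#' @return List with `rep1`, `rep2` (`GRanges`), and `truthPeaks`
#'   (data.frame: peak id, intended gene, TSS offset of the peak centre in
#'   gene orientation, on_carrier flag).
#' @export
simulatePeaks <- function(ann, config = ann$config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed + 1L, simulatePeaksImpl(ann, config))
}

simulatePeaksImpl <- function(ann, cfg) {
  genes <- ann$genes
  tes <- ann$tes
  if (max(cfg$peak_length) > cfg$promoter_length)
    stop("peak length exceeds promoter length", call. = FALSE)
  gstr <- as.character(strand(genes))
  names(gstr) <- genes$gene_id
  tssOf <- setNames(genes$tss, genes$gene_id)
  chromOf <- setNames(as.character(seqnames(genes)), genes$gene_id)

  nCommon <- round((1 - cfg$replicate_specific_fraction) * cfg$peak_count)
  nTarget <- min(round(cfg$peak_motif_targeting * cfg$peak_count), nCommon)

  carriers <- tes[tes$motif_carrier]
  # match each carrier to the gene whose promoter hosts it
  prom <- promoterUniverse(genes, span = cfg$promoter_length)
  hits <- findOverlaps(carriers, prom, ignore.strand = TRUE)
  carrierGene <- rep(NA_character_, length(carriers))
  carrierGene[queryHits(hits)] <- prom$gene_id[subjectHits(hits)]
  ok <- !is.na(carrierGene)
  carriers <- carriers[ok]
  carrierGene <- carrierGene[ok]
  if (nTarget > 0 && length(carriers) == 0L)
    stop("no motif-carrying promoter TEs available for peak targeting",
         call. = FALSE)

  mkPeak <- function(center, chrom) {
    len <- round(runif(1, cfg$peak_length[1L], cfg$peak_length[2L]))
    st <- max(1, center - floor(len / 2))
    GRanges(chrom, IRanges(st, st + len - 1))
  }
  peakRows <- vector("list", nCommon)
  pick <- if (nTarget > 0)
    sample(seq_along(carriers), nTarget, replace = nTarget > length(carriers))
  else integer()
  for (i in seq_len(nCommon)) {
    if (i <= nTarget) {
      te <- carriers[pick[i]]
      center <- te$motif_start + 4L
      gene <- carrierGene[pick[i]]
      chrom <- as.character(seqnames(te))
      onCarrier <- TRUE
    } else {
      g <- sample.int(length(genes), 1L)
      gene <- genes$gene_id[g]
      chrom <- chromOf[gene]
      off <- round(runif(1, 1, cfg$promoter_length - max(cfg$peak_length)))
      center <- if (gstr[gene] == "+") tssOf[gene] - off else
        tssOf[gene] + off
      onCarrier <- FALSE
    }
    pk <- mkPeak(center, chrom)
    pk$gene <- gene
    pk$on_carrier <- onCarrier
    peakRows[[i]] <- pk
  }
  common <- do.call(c, peakRows)
  common$peak_id <- sprintf("peak_%04d", seq_len(nCommon))

  nSpec <- cfg$peak_count - nCommon
  mkBackground <- function(n, prefix) {
    if (n == 0L) return(GRanges())
    out <- vector("list", n)
    for (i in seq_len(n)) {
      g <- sample.int(length(genes), 1L)
      gene <- genes$gene_id[g]
      off <- round(runif(1, 1, cfg$promoter_length - max(cfg$peak_length)))
      center <- if (gstr[gene] == "+") tssOf[gene] - off else
        tssOf[gene] + off
      pk <- mkPeak(center, chromOf[gene])
      pk$gene <- gene
      pk$on_carrier <- FALSE
      out[[i]] <- pk
    }
    gr <- do.call(c, out)
    gr$peak_id <- sprintf("%s_%04d", prefix, seq_len(n))
    gr
  }
  spec1 <- mkBackground(nSpec, "r1only")
  spec2 <- mkBackground(nSpec, "r2only")

  shift2 <- if (cfg$replicate_jitter > 0)
    round(runif(nCommon, -cfg$replicate_jitter, cfg$replicate_jitter))
  else rep(0L, nCommon)
  common2 <- shift(common, as.integer(shift2))

  rep1 <- sortIntervals(c(common, spec1))
  rep2 <- sortIntervals(c(common2, spec2))

  mid <- intervalMid(common)
  tssOffset <- ifelse(gstr[common$gene] == "-",
                      tssOf[common$gene] - mid, mid - tssOf[common$gene])
  truthPeaks <- data.frame(peak_id = common$peak_id,
                           gene_id = unname(common$gene),
                           tss_offset = unname(tssOffset),
                           on_carrier = common$on_carrier)
  list(rep1 = rep1, rep2 = rep2, truthPeaks = truthPeaks)
}

# expected maternal fraction and planted means, on the odds scale
crossOdds <- function(cross) {
  switch(cross, "2x" = 2, "3x_paternal_excess" = 1,
         stop("unknown cross type: ", cross, call. = FALSE))
}

#' Simulate allele-specific counts and chromatin signal tracks
#'
#' Maternal read counts follow a beta-binomial with cross-specific
#' expected maternal fraction (2/3 in 2x seeds, 1/2 in 3x paternal-excess
#' seeds); planted MEGs/PEGs have their expectation moved to
#' `label_margin` times the four-fold classification threshold on the
#' odds scale. H3K27me3 tracks realize two archetypes per binding site:
#' cluster 1 sites show flank-enriched, centre-depleted maternal signal
#' over a flat paternal background, cluster 2 sites are flat-depleted on
#' both alleles. CG methylation tracks plant a paternal offset on
#' MEG-associated sites.
#'
#' @param ann Output of [simulateAnnotation()].
#' @param peaks Output of [simulatePeaks()].
#' @param config The same [simulationConfig()].
#' @return List with `counts` (data.frame gene/cross/replicate/maternal/
#'   paternal), `truthImprinting` (gene -> label), `tracks` (named list of
#'   `GRanges` signal tracks: `h3k27me3_maternal`, `h3k27me3_paternal`,
#'   `h3k27me3_total`, `meth_maternal`, `meth_paternal`), `siteWindows`
#'   (`GRanges` of the profiled windows, one per common peak) and
#'   `truthSites` (site id, archetype, imprinting group of the intended
#'   gene).
#' @export
simulateAllelicData <- function(ann, peaks, config = ann$config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed + 2L, simulateAllelicDataImpl(ann, peaks, config))
}

simulateAllelicDataImpl <- function(ann, peaks, cfg) {
  genes <- ann$genes
  nExpr <- min(cfg$n_expressed_genes, length(genes))
  exprGenes <- sort(sample(as.character(genes$gene_id), nExpr))
  nMeg <- round(cfg$meg_fraction * nExpr)
  nPeg <- round(cfg$peg_fraction * nExpr)
  lab <- rep("biallelic", nExpr)
  imprinted <- sample.int(nExpr, nMeg + nPeg)
  lab[imprinted[seq_len(nMeg)]] <- "MEG"
  if (nPeg > 0) lab[imprinted[nMeg + seq_len(nPeg)]] <- "PEG"
  names(lab) <- exprGenes

  drawMaternal <- function(n, mu) {
    if (cfg$deterministic_counts) return(round(mu * n))
    rho <- cfg$allelic_dispersion
    if (rho == 0) return(rbinom(length(n), n, mu))
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    p <- rbeta(length(n), a, b)
    rbinom(length(n), n, p)
  }

  rows <- list()
  for (cross in c("2x", "3x_paternal_excess")) {
    omega <- crossOdds(cross)
    for (g in exprGenes) {
      # planted imprinted genes sit at label_margin times the four-fold
      # classification threshold, measured on the log-odds scale where
      # the fold-deviation is defined (margin 1 = exactly at threshold)
      odds <- switch(lab[[g]],
                     MEG = omega * 4^cfg$label_margin,
                     PEG = omega / 4^cfg$label_margin,
                     biallelic = omega)
      mu <- odds / (odds + 1)
      for (repi in 1:2) {
        depth <- round(runif(1, cfg$depth_range[1L], cfg$depth_range[2L]))
        m <- drawMaternal(depth, mu)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, cross = cross, replicate = repi,
          maternal = as.integer(m), paternal = as.integer(depth - m))
      }
    }
  }
  counts <- do.call(rbind, rows)

  # --- signal tracks around the common-peak centres ---
  truthPeaks <- peaks$truthPeaks
  common <- peaks$rep1[match(truthPeaks$peak_id, peaks$rep1$peak_id)]
  mid <- intervalMid(common)
  half <- cfg$signal_window / 2
  nbin <- cfg$signal_window / cfg$signal_bin
  keep <- mid - half >= 0 & mid + half <= cfg$chrom_length
  # one chromatin locus per window: drop sites whose window would overlap
  # an already selected one (each locus carries a single archetype)
  ord <- order(as.character(seqnames(common)), mid)
  lastEnd <- -Inf
  lastChr <- ""
  for (i in ord) {
    if (!keep[i]) next
    ch <- as.character(seqnames(common))[i]
    if (ch == lastChr && mid[i] - half + 1 <= lastEnd) {
      keep[i] <- FALSE
    } else {
      lastChr <- ch
      lastEnd <- mid[i] + half
    }
  }
  common <- common[keep]
  mid <- mid[keep]
  truthPeaks <- truthPeaks[keep, , drop = FALSE]
  ns <- length(common)
  arch <- ifelse(runif(ns) < cfg$cluster1_fraction, "cluster1", "cluster2")
  group <- ifelse(truthPeaks$gene_id %in% names(lab),
                  unname(lab[truthPeaks$gene_id]), "biallelic")
  group <- c(MEG = "MEG", PEG = "PEG",
             biallelic = "non_imprinted")[group]

  binOffsets <- seq(-half, half - cfg$signal_bin, by = cfg$signal_bin)
  centerMask <- abs(binOffsets + cfg$signal_bin / 2) <=
    cfg$center_depletion_width / 2
  depleted <- 0.05
  mkTrack <- function(values, chrom, starts) {
    gr <- GRanges(chrom, IRanges(starts, width = cfg$signal_bin))
    gr$score <- values
    gr
  }
  trackRows <- list(h3k27me3_maternal = list(), h3k27me3_paternal = list(),
                    meth_maternal = list(), meth_paternal = list())
  for (i in seq_len(ns)) {
    starts <- mid[i] + binOffsets + 1  # 1-based bin starts
    noise <- function() rnorm(nbin, 0, cfg$signal_noise_sd)
    if (arch[i] == "cluster1") {
      mat <- ifelse(centerMask, depleted,
                    cfg$signal_baseline + cfg$flank_amplitude) + noise()
      pat <- cfg$signal_baseline + noise()
    } else {
      mat <- depleted + noise()
      pat <- depleted + noise()
    }
    methM <- pmin(1, pmax(0, cfg$meth_baseline +
                            rnorm(nbin, 0, cfg$meth_noise_sd)))
    offs <- if (group[i] == "MEG") cfg$meth_meg_paternal_offset else 0
    methP <- pmin(1, pmax(0, cfg$meth_baseline + offs +
                            rnorm(nbin, 0, cfg$meth_noise_sd)))
    ch <- as.character(seqnames(common))[i]
    trackRows$h3k27me3_maternal[[i]] <- mkTrack(mat, ch, starts)
    trackRows$h3k27me3_paternal[[i]] <- mkTrack(pat, ch, starts)
    trackRows$meth_maternal[[i]] <- mkTrack(methM, ch, starts)
    trackRows$meth_paternal[[i]] <- mkTrack(methP, ch, starts)
  }
  tracks <- lapply(trackRows, function(l) do.call(c, l))
  tot <- tracks$h3k27me3_maternal
  tot$score <- tot$score + tracks$h3k27me3_paternal$score
  tracks$h3k27me3_total <- tot

  siteWindows <- GRanges(seqnames(common),
                         IRanges(mid - half + 1, mid + half))
  siteWindows$site_id <- common$peak_id
  truthSites <- data.frame(site_id = common$peak_id, archetype = arch,
                           group = group)
  truthImprinting <- data.frame(gene_id = exprGenes, label = unname(lab))
  list(counts = counts, truthImprinting = truthImprinting,
       tracks = tracks, siteWindows = siteWindows, truthSites = truthSites)
}

#' Generate and write the full synthetic bundle
#'
#' Runs [simulateAnnotation()], [simulatePeaks()] and
#' [simulateAllelicData()] under one master seed and writes every product
#' in its standard format (FASTA, GFF3, BED, bedGraph, TSV) plus the
#' machine-readable truth tables and the configuration as YAML. Rerunning
#' with the same configuration yields byte-identical files.
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle (annotation, peaks, allelic
#'   data and file paths).
#' @export
simulateAll <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulateAnnotation(config)
  peaks <- simulatePeaks(ann, config)
  allelic <- simulateAllelicData(ann, peaks, config)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    tes = file.path(dir, "tes.bed"),
    rep1 = file.path(dir, "peaks_rep1.bed"),
    rep2 = file.path(dir, "peaks_rep2.bed"),
    counts = file.path(dir, "allelic_counts.tsv"),
    truth_te = file.path(dir, "truth_te.tsv"),
    truth_peaks = file.path(dir, "truth_peaks.tsv"),
    truth_imprinting = file.path(dir, "truth_imprinting.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    config = file.path(dir, "config.yaml"))
  writeXStringSet(ann$genome, paths$genome)
  writeGff3(ann$genes, paths$genes)
  writeBed(ann$tes, paths$tes, feature = ann$tes$superfamily)
  writeBed(peaks$rep1, paths$rep1, feature = peaks$rep1$peak_id)
  writeBed(peaks$rep2, paths$rep2, feature = peaks$rep2$peak_id)
  writeTsv(allelic$counts, paths$counts)
  writeTsv(ann$truthTe, paths$truth_te)
  writeTsv(peaks$truthPeaks, paths$truth_peaks)
  writeTsv(allelic$truthImprinting, paths$truth_imprinting)
  writeTsv(allelic$truthSites, paths$truth_sites)
  for (tn in names(allelic$tracks)) {
    paths[[tn]] <- file.path(dir, paste0(tn, ".bedGraph"))
    writeBedGraph(allelic$tracks[[tn]], paths[[tn]])
  }
  cfgOut <- unclass(config)
  cfgOut$te_counts <- as.list(cfgOut$te_counts)
  yaml::write_yaml(cfgOut, paths$config)
  invisible(list(annotation = ann, peaks = peaks, allelic = allelic,
                 paths = paths))
}
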