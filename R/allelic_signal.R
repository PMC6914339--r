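#' Bin a signal track around binding-site centres
#'
#' Quantifies a bedGraph-style track in fixed-width bins (default 50 bp)
#' across a window (default 2 kb) centred on each site's midpoint. A bin's
#' value is the coverage-weighted mean of the track over the bin; bins
#' with no track coverage are `NA` (missing, never zero-filled). Sites
#' whose window would run past a chromosome end are dropped and reported
#' via the `dropped` attribute.
#'
#' @param track `GRanges` with a numeric `score` (see [readBedGraph()]).
#' @param sitesGr `GRanges` of sites (or a [BindingSiteSet-class]).
#' @param window,bin Window and bin width in bases; `window` must be a
#'   multiple of `bin`.
#' @return Numeric matrix (sites x bins), rownames from site names,
#'   column names the bin-start offsets relative to the window centre.
#'   Attributes: `metagene` (per-bin across-site mean, `NA` bins ignored)
#'   and `dropped` (indices of discarded sites).
#' @export
binSignal <- function(track, sitesGr, window = 2000, bin = 50) {
  if (is(sitesGr, "BindingSiteSet")) sitesGr <- sites(sitesGr)
  if (window %% bin != 0)
    stop("window must be divisible by bin", call. = FALSE)
  nbin <- window / bin
  half <- window / 2
  mid <- intervalMid(sitesGr)
  sl <- seqlengths(sitesGr)
  if (all(is.na(sl))) sl <- seqlengths(track)
  chrEnd <- sl[as.character(seqnames(sitesGr))]
  tooLeft <- mid - half + 1 < 1
  tooRight <- !is.na(chrEnd) & (mid + half > chrEnd)
  dropped <- as.integer(which(tooLeft | tooRight))
  keep <- setdiff(seq_along(sitesGr), dropped)
  binOffsets <- seq(-half, half - bin, by = bin)
  m <- matrix(NA_real_, length(keep), nbin,
              dimnames = list(siteNames(sitesGr)[keep],
                              as.character(binOffsets)))
  if (length(keep)) {
    binsList <- lapply(seq_along(keep), function(i) {
      s <- keep[i]
      GRanges(seqnames(sitesGr)[s],
              IRanges(mid[s] + binOffsets + 1, width = bin))
    })
    bins <- do.call(c, binsList)
    hits <- findOverlaps(bins, track, ignore.strand = TRUE)
    if (length(hits)) {
      qh <- queryHits(hits)
      sh <- subjectHits(hits)
      w <- pmin(end(bins)[qh], end(track)[sh]) -
        pmax(start(bins)[qh], start(track)[sh]) + 1
      num <- tapply(w * track$score[sh], qh, sum)
      den <- tapply(w, qh, sum)
      idx <- as.integer(names(num))
      vals <- rep(NA_real_, length(bins))
      vals[idx] <- num / den
      m[] <- matrix(vals, nrow = length(keep), ncol = nbin, byrow = TRUE)
    }
  }
  attr(m, "metagene") <- colMeans(m, na.rm = TRUE)
  attr(m, "dropped") <- dropped
  m
}

siteNames <- function(gr) {
  if (!is.null(gr$site_id)) as.character(gr$site_id)
  else if (!is.null(gr$name)) as.character(gr$name)
  else sprintf("site_%05d", seq_along(gr))
}

#' Metagene profile of a signal matrix
#'
#' @param m Matrix from [binSignal()].
#' @return Per-bin across-site mean (missing bins excluded).
#' @export
metagene <- function(m) colMeans(m, na.rm = TRUE)

#' Cluster binding sites by chromatin-signal shape
#'
#' k-means (k = 2 by default) on the binned H3K27me3 signal, separating
#' sites with flank-enriched, centre-depleted profiles from flat-depleted
#' ones. Cluster numbering is deterministic: cluster 1 is the cluster
#' with the higher mean flank signal (outer quarters of the window), so
#' labels are stable across seeds for well-separated profiles.
#'
#' @param m Signal matrix (sites x bins); rows with missing bins are
#'   dropped by the clustering and reported.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @return List: `labels` (named integer per clustered site), `centroids`,
#'   `dropped`, `order` (row order for heatmap display: within cluster,
#'   by decreasing mean signal), `degenerate` (TRUE when all rows are
#'   identical).
#' @export
clusterSites <- function(m, k = 2, seed = 1L) {
  degenerate <- nrow(unique(as.data.frame(m))) < k
  if (degenerate) {
    labels <- setNames(rep(1L, nrow(m)), rownames(m))
    return(list(labels = labels, centroids = NULL, dropped = integer(),
                order = order(-rowMeans(m, na.rm = TRUE)),
                degenerate = TRUE))
  }
  fit <- kmeansCluster(m, k = k, seed = seed)
  labels <- fit$labels
  nbin <- ncol(m)
  flank <- c(seq_len(floor(nbin / 4)),
             seq(nbin - floor(nbin / 4) + 1, nbin))
  flankMean <- vapply(seq_len(k), function(cl)
    mean(fit$centroids[cl, flank]), 0)
  remap <- order(-flankMean)           # new label 1 = highest flank signal
  labels <- match(labels, remap)
  names(labels) <- rownames(m)[setdiff(seq_len(nrow(m)), fit$dropped)]
  rowMean <- rowMeans(m, na.rm = TRUE)
  kept <- setdiff(seq_len(nrow(m)), fit$dropped)
  ord <- kept[order(labels, -rowMean[kept])]
  list(labels = labels, centroids = fit$centroids[remap, , drop = FALSE],
       dropped = fit$dropped, order = ord, degenerate = FALSE)
}

#' Standardize a signal track to z-scores
#'
#' Standardizes the track's bin values to mean 0 and standard deviation 1
#' over all bins, weighting by bin width, giving the genome-wide z-score
#' track used for gene-body scoring.
#'
#' @param track `GRanges` with `score`.
#' @param center,scale Optional externally supplied standardization
#'   constants (e.g. from a genome-wide reference track); defaults are
#'   the track's own width-weighted mean and standard deviation.
#' @return The track with `score` replaced by z-scores.
#' @export
zscoreTrack <- function(track, center = NULL, scale = NULL) {
  w <- width(track)
  mu <- if (is.null(center)) sum(w * track$score) / sum(w) else center
  v <- sum(w * (track$score - mu)^2) / sum(w)
  sdv <- if (is.null(scale)) sqrt(v) else scale
  track$score <- if (sdv > 0) (track$score - mu) / sdv else
    rep(0, length(track))
  track
}

#' Mean H3K27me3 z-score over gene bodies, per allele
#'
#' For each gene, the mean of the z-score track over the gene body
#' (coverage-weighted across overlapping track bins). Genes with no
#' covered bins are omitted and reported. When two allele tracks are
#' supplied, group contrasts (e.g. maternal PEG alleles in 2x vs 3x
#' seeds) can then be run with [compareGroupsMW()].
#'
#' @param track Z-score `GRanges` track for one allele (see
#'   [zscoreTrack()]).
#' @param genes `GRanges` with `gene_id`.
#' @return `data.frame` with `gene_id` and `score`; attribute `omitted`
#'   lists genes with zero covered bins.
#' @export
geneBodyScore <- function(track, genes) {
  hits <- findOverlaps(genes, track, ignore.strand = TRUE)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  w <- pmin(end(genes)[qh], end(track)[sh]) -
    pmax(start(genes)[qh], start(track)[sh]) + 1
  num <- tapply(w * track$score[sh], qh, sum)
  den <- tapply(w, qh, sum)
  idx <- as.integer(names(num))
  out <- data.frame(gene_id = as.character(genes$gene_id)[idx],
                    score = as.numeric(num / den))
  attr(out, "omitted") <-
    as.character(genes$gene_id)[setdiff(seq_along(genes), idx)]
  out
}

#' Allele-specific CG methylation contrast across site groups
#'
#' Summarizes each site's window-mean CG methylation per parental allele
#' and compares the distributions across site groups (MEG-, PEG-,
#' non-imprinted-associated) and between alleles within each group, with
#' two-tailed Mann-Whitney tests.
#'
#' @param methMats Named list of matrices from [binSignal()], one per
#'   allele (e.g. `maternal`, `paternal`); equal row sets.
#' @param groups Character/factor vector of site groups, one per row.
#' @return List: `siteMeans` (data.frame site, group, allele, mean),
#'   `betweenGroups` (pairwise MW p per allele), `betweenAlleles` (MW p
#'   per group).
#' @export
methylationContrast <- function(methMats, groups) {
  stopifnot(is.list(methMats), !is.null(names(methMats)))
  groups <- as.character(groups)
  rows <- lapply(names(methMats), function(al) {
    m <- methMats[[al]]
    if (length(groups) != nrow(m))
      stop("groups must have one entry per site", call. = FALSE)
    data.frame(site = rownames(m), group = groups, allele = al,
               mean = rowMeans(m, na.rm = TRUE))
  })
  siteMeans <- do.call(rbind, rows)
  gl <- sort(unique(groups))
  if (any(table(groups) == 0L) || length(gl) < 1L)
    stop("site groups must be non-empty", call. = FALSE)
  betweenGroups <- NULL
  if (length(gl) >= 2L) {
    prs <- combn(gl, 2L)
    betweenGroups <- do.call(rbind, lapply(names(methMats), function(al) {
      do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        a <- siteMeans$mean[siteMeans$allele == al &
                              siteMeans$group == prs[1L, j]]
        b <- siteMeans$mean[siteMeans$allele == al &
                              siteMeans$group == prs[2L, j]]
        data.frame(allele = al, groupA = prs[1L, j], groupB = prs[2L, j],
                   p = compareGroupsMW(a, b)$p)
      }))
    }))
  }
  betweenAlleles <- NULL
  if (length(methMats) == 2L) {
    al <- names(methMats)
    betweenAlleles <- do.call(rbind, lapply(gl, function(g) {
      a <- siteMeans$mean[siteMeans$allele == al[1L] &
                            siteMeans$group == g]
      b <- siteMeans$mean[siteMeans$allele == al[2L] &
                            siteMeans$group == g]
      data.frame(group = g, alleleA = al[1L], alleleB = al[2L],
                 p = compareGroupsMW(a, b)$p,
                 meanA = mean(a), meanB = mean(b))
    }))
  }
  list(siteMeans = siteMeans, betweenGroups = betweenGroups,
       betweenAlleles = betweenAlleles)
}

#' Assemble binned allele channels into a SummarizedExperiment
#'
#' @param mats Named list of matrices from [binSignal()] with identical
#'   dimensions (e.g. maternal, paternal, total).
#' @param sitesGr Optional `GRanges` of the profiled sites (rowRanges).
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   per channel.
#' @export
signalExperiment <- function(mats, sitesGr = NULL) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all channel matrices must share dimensions", call. = FALSE)
  if (!is.null(sitesGr)) {
    keep <- setdiff(seq_along(sitesGr), attr(mats[[1L]], "dropped"))
    SummarizedExperiment(assays = lapply(mats, unclass),
                         rowRanges = sitesGr[keep])
  } else {
    SummarizedExperiment(assays = lapply(mats, unclass))
  }
}
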