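#' Define replicate-supported binding sites
#'
#' Only peak regions supported by both biological replicates are carried
#' forward: for every overlapping pair of replicate-1 and replicate-2 peaks
#' the pairwise intersection interval is emitted, and overlapping emissions
#' are merged. The per-replicate reproducibility (fraction of a replicate's
#' peaks that overlap the other replicate) is recorded alongside.
#'
#' @param rep1,rep2 Non-empty peak `GRanges`, one per replicate.
#' @return A [BindingSiteSet-class] object.
#' @examples
#' r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
#' r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 400))
#' sites(commonPeaks(r1, r2))   # the intersection 201-300
#' @export
commonPeaks <- function(rep1, rep2) {
  if (length(rep1) == 0L || length(rep2) == 0L)
    stop("both replicate peak sets must be non-empty", call. = FALSE)
  hits <- findOverlaps(rep1, rep2, ignore.strand = TRUE)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  if (length(qh)) {
    inter <- GRanges(seqnames(rep1)[qh],
                     IRanges(pmax(start(rep1)[qh], start(rep2)[sh]),
                             pmin(end(rep1)[qh], end(rep2)[sh])))
    # merge only genuinely overlapping emissions (adjacency is not overlap)
    merged <- reduce(inter, min.gapwidth = 0L)
    m1 <- findOverlaps(merged, rep1, ignore.strand = TRUE)
    m2 <- findOverlaps(merged, rep2, ignore.strand = TRUE)
    merged$rep1_peaks <- vapply(seq_along(merged), function(i)
      paste(subjectHits(m1)[queryHits(m1) == i], collapse = ","), "")
    merged$rep2_peaks <- vapply(seq_along(merged), function(i)
      paste(subjectHits(m2)[queryHits(m2) == i], collapse = ","), "")
    merged$name <- sprintf("site_%05d", seq_along(merged))
  } else {
    merged <- GRanges()
  }
  rep_frac <- c(rep1 = mean(countOverlaps(rep1, rep2,
                                          ignore.strand = TRUE) > 0L),
                rep2 = mean(countOverlaps(rep2, rep1,
                                          ignore.strand = TRUE) > 0L))
  new("BindingSiteSet", sites = merged, rep1 = rep1, rep2 = rep2,
      reproducibility = rep_frac)
}

#' Annotate binding sites to the nearest TSS
#'
#' Each site is anchored at its midpoint and assigned the gene whose TSS
#' minimises the absolute signed distance. Distances are orientation-aware:
#' negative means upstream of the TSS in the gene's own orientation, so a
#' site 250 bp genomically downstream of a minus-strand TSS has distance
#' -250. The associated feature class is `promoter` when the midpoint lies
#' within `promoterSpan` bases upstream of the TSS, `gene_body` when it
#' falls inside the nearest gene's body, and `intergenic` otherwise.
#'
#' @param x A [BindingSiteSet-class] or a `GRanges` of sites.
#' @param genes `GRanges` of gene models with `gene_id` and `tss` columns
#'   (see [readGenes()]).
#' @param promoterSpan Upstream span classified as promoter (default 3000).
#' @return A `data.frame` with one row per site: `site`, `chrom`,
#'   `start`, `end`, `midpoint`, `gene_id`, `distance`, `feature`.
#' @export
annotateSites <- function(x, genes, promoterSpan = 3000) {
  siteGr <- if (is(x, "BindingSiteSet")) sites(x) else x
  if (length(genes) == 0L) stop("need at least one gene", call. = FALSE)
  if (length(siteGr) == 0L)
    return(data.frame(site = character(), chrom = character(),
                      start = integer(), end = integer(),
                      midpoint = integer(), gene_id = character(),
                      distance = numeric(), feature = character()))
  mid <- intervalMid(siteGr)
  schr <- as.character(seqnames(siteGr))
  gchr <- as.character(seqnames(genes))
  gstr <- as.character(strand(genes))
  gid <- as.character(genes$gene_id)
  n <- length(siteGr)
  out_gene <- character(n)
  out_dist <- numeric(n)
  out_feat <- character(n)
  for (chr in unique(schr)) {
    si <- which(schr == chr)
    gi <- which(gchr == chr)
    if (length(gi) == 0L) gi <- seq_along(genes)  # fall back to all genes
    tss <- genes$tss[gi]
    for (i in si) {
      gdist <- ifelse(gstr[gi] == "-", tss - mid[i], mid[i] - tss)
      # genes on other chromosomes can never be nearest when gi is per-chrom
      best <- which(abs(gdist) == min(abs(gdist)))
      if (length(best) > 1L) best <- best[order(gid[gi][best])[1L]]
      g <- gi[best]
      d <- gdist[best]
      inBody <- gchr[g] == chr && mid[i] >= start(genes)[g] &&
        mid[i] <= end(genes)[g]
      feat <- if (d >= -promoterSpan && d < 0) "promoter"
              else if (inBody) "gene_body" else "intergenic"
      out_gene[i] <- gid[g]
      out_dist[i] <- d
      out_feat[i] <- feat
    }
  }
  nm <- if (!is.null(siteGr$name)) as.character(siteGr$name) else
    sprintf("site_%05d", seq_len(n))
  data.frame(site = nm, chrom = schr, start = start(siteGr),
             end = end(siteGr), midpoint = mid, gene_id = out_gene,
             distance = out_dist, feature = out_feat)
}

#' Call target genes from site annotations
#'
#' A gene is a target when at least one binding site lies within the
#' TSS-proximal window, `upstream` bases 5' to `downstream` bases 3' of its
#' TSS (both boundaries inclusive). The default window of 1.5 kb upstream
#' to 0.5 kb downstream keeps the high-confidence promoter-proximal sites
#' and discards distal false positives.
#'
#' @param annotations Output of [annotateSites()].
#' @param upstream,downstream Non-negative window half-widths in bases.
#' @return Sorted character vector of unique target gene ids.
#' @export
callTargets <- function(annotations, upstream = 1500, downstream = 500) {
  assertScalarNumber(upstream, "upstream", min = 0)
  assertScalarNumber(downstream, "downstream", min = 0)
  keep <- annotations$distance >= -upstream &
    annotations$distance <= downstream
  sort(unique(annotations$gene_id[keep]))
}
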