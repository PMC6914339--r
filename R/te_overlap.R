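# --- fast numeric core ------------------------------------------------
# The permutation test runs tens of thousands of shuffles, so the inner
# loop works on plain integer vectors; the GRanges API wraps this core.

# promoters as parallel vectors (chromosome code, start, width)
prepPromoters <- function(promoters) {
  list(chrom = as.integer(factor(as.character(seqnames(promoters)))),
       chromLevels = levels(factor(as.character(seqnames(promoters)))),
       start = start(promoters), width = width(promoters))
}

# one shuffle: for each site length pick a promoter able to contain it
# (uniformly among eligible promoters) and a uniform offset inside it
fastShuffle <- function(w, pp) {
  n <- length(w)
  chrom <- integer(n)
  st <- integer(n)
  for (len in unique(w)) {
    idx <- which(w == len)
    elig <- which(pp$width >= len)
    if (length(elig) == 0L)
      stop("a site is longer than every promoter; cannot shuffle",
           call. = FALSE)
    pick <- elig[sample.int(length(elig), length(idx), replace = TRUE)]
    off <- floor(runif(length(idx)) * (pp$width[pick] - len + 1))
    chrom[idx] <- pp$chrom[pick]
    st[idx] <- pp$start[pick] + as.integer(off)
  }
  list(chrom = chrom, start = st, end = st + w - 1L)
}

# merged (disjoint, sorted) feature intervals per chromosome code
prepFeature <- function(feature, chromLevels) {
  red <- reduce(feature, ignore.strand = TRUE)
  code <- match(as.character(seqnames(red)), chromLevels)
  keep <- !is.na(code)
  red <- red[keep]
  code <- code[keep]
  lapply(seq_along(chromLevels), function(ci) {
    sel <- code == ci
    list(start = start(red)[sel], end = end(red)[sel])
  })
}

# fraction of query intervals overlapping >= 1 merged feature interval
fastOverlapFrac <- function(chrom, st, en, featPrep) {
  hit <- logical(length(st))
  for (ci in unique(chrom)) {
    f <- featPrep[[ci]]
    sel <- chrom == ci
    if (length(f$start) == 0L) next
    idx <- findInterval(en[sel], f$start)
    hit[sel] <- idx >= 1L & f$end[pmax(idx, 1L)] >= st[sel]
  }
  mean(hit)
}

#' Shuffle binding sites into the promoter universe
#'
#' Builds a random binding-site set with the same cardinality and the same
#' multiset of lengths as the observed set. Each random site is placed
#' wholly within one promoter, chosen uniformly among the promoters large
#' enough to contain it, at a uniform offset. This is the null model for
#' the TE-overlap permutation test: what overlap would sites of this size
#' distribution show if they fell on random gene promoters?
#'
#' @param siteGr `GRanges` of observed sites (a [BindingSiteSet-class] is
#'   also accepted).
#' @param promoters `GRanges` promoter universe.
#' @return `GRanges` of shuffled sites.
#' @export
shuffleSites <- function(siteGr, promoters) {
  if (is(siteGr, "BindingSiteSet")) siteGr <- sites(siteGr)
  pp <- prepPromoters(promoters)
  sh <- fastShuffle(width(siteGr), pp)
  GRanges(pp$chromLevels[sh$chrom], IRanges(sh$start, sh$end))
}

#' Monte Carlo permutation test of binding-site/TE overlap
#'
#' For each TE feature (superfamily or family) the observed fraction of
#' binding sites overlapping at least one TE copy is compared with a null
#' distribution obtained by repeatedly shuffling a size-matched random
#' site set across gene promoters ([shuffleSites()]). The empirical
#' p-value uses the add-one rule (r + 1)/(n + 1), where r counts null
#' values at least as extreme as the observed fraction, so it is never
#' exactly zero.
#'
#' @param x Observed sites (`GRanges` or [BindingSiteSet-class]).
#' @param teByFeature Named list of `GRanges`, one per TE feature.
#' @param promoters Promoter universe `GRanges`.
#' @param nIter Number of shuffles (the study scale is 10000; smaller
#'   values are fine for exploration).
#' @param seed Integer seed governing the shuffles.
#' @param alternative `"enrichment"` (null >= observed counts toward r) or
#'   `"depletion"`.
#' @return `data.frame` with one row per feature: `feature`, `observed`,
#'   `null_mean`, `null_sd`, `z` (NA when `null_sd` is 0), `p`, `n_iter`,
#'   `seed`.
#' @export
permutationTest <- function(x, teByFeature, promoters, nIter = 10000,
                            seed = 1L,
                            alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  assertScalarNumber(nIter, "nIter", min = 1)
  if (is(x, "BindingSiteSet")) x <- sites(x)
  stopifnot(is.list(teByFeature), !is.null(names(teByFeature)))
  feats <- names(teByFeature)
  observed <- vapply(feats, function(f) overlapFraction(x, teByFeature[[f]]),
                     0)
  pp <- prepPromoters(promoters)
  featPrep <- lapply(teByFeature, prepFeature,
                     chromLevels = pp$chromLevels)
  w <- width(x)
  null <- withSeed(seed, {
    vapply(seq_len(nIter), function(i) {
      sh <- fastShuffle(w, pp)
      vapply(featPrep, function(fp)
        fastOverlapFrac(sh$chrom, sh$start, sh$end, fp),
        0)
    }, numeric(length(feats)))
  })
  null <- matrix(null, nrow = length(feats))
  res <- lapply(seq_along(feats), function(i) {
    nv <- null[i, ]
    mu <- mean(nv)
    sdv <- if (nIter > 1L) sd(nv) else 0
    r <- if (alternative == "enrichment") sum(nv >= observed[i])
         else sum(nv <= observed[i])
    data.frame(feature = feats[i], observed = observed[i], null_mean = mu,
               null_sd = sdv,
               z = if (sdv > 0) (observed[i] - mu) / sdv else NA_real_,
               p = (r + 1) / (nIter + 1), n_iter = nIter,
               seed = as.integer(seed))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Promoter universe for shuffling
#'
#' The `span` bases upstream of every TSS, in gene orientation, clipped at
#' chromosome starts (and ends, when sequence lengths are known). By
#' default neighbouring gene bodies are not clipped out, matching the
#' simple "promoter region of all genes" universe.
#'
#' @param genes `GRanges` with `gene_id` and `tss` columns.
#' @param span Promoter length in bases (default 3000).
#' @param clipGeneBodies Also subtract overlapping gene bodies
#'   (default FALSE).
#' @return `GRanges` of promoter spans with `gene_id`.
#' @export
promoterUniverse <- function(genes, span = 3000, clipGeneBodies = FALSE) {
  minus <- as.character(strand(genes)) == "-"
  st <- ifelse(minus, genes$tss + 1, genes$tss - span)
  en <- ifelse(minus, genes$tss + span, genes$tss - 1)
  st <- pmax(st, 1)
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  if (!all(is.na(sl))) en <- pmin(en, ifelse(is.na(sl), en, sl))
  keep <- en >= st
  prom <- GRanges(seqnames(genes)[keep], IRanges(st[keep], en[keep]),
                  strand = strand(genes)[keep])
  prom$gene_id <- genes$gene_id[keep]
  if (clipGeneBodies) {
    frag <- setdiff(prom, granges(genes), ignore.strand = TRUE)
    hits <- findOverlaps(frag, prom, ignore.strand = TRUE)
    frag$gene_id <- NA_character_
    frag$gene_id[queryHits(hits)] <- prom$gene_id[subjectHits(hits)]
    prom <- frag
  }
  sortIntervals(prom)
}
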