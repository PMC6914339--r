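#' Hypergeometric enrichment test
#'
#' Over-representation p-value P(X >= k) for drawing `k` category members
#' in a set of size `n` from a universe of `N` genes containing `K`
#' category members (under-representation P(X <= k) by `tail`).
#'
#' @param k Observed category members in the set.
#' @param n Set size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @param tail `"over"` or `"under"`.
#' @return The p-value.
#' @export
hypergeomTest <- function(k, n, K, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (k < 0 || n < 0 || K < 0 || n > N || K > N || k > min(n, K))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  if (tail == "over") phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Transcription-factor family enrichment among target genes
#'
#' For each TF family, the proportion of targeted TFs that belong to the
#' family is compared with the proportion of all TFs in the genome that
#' belong to it; the log2 fold-change of these two normalized ratios is
#' reported alongside a hypergeometric p-value. Families with five or
#' fewer members genome-wide are excluded.
#'
#' @param targetTfIds TF gene ids among the targets.
#' @param familyMap Named character vector: TF id -> family.
#' @param minFamilySize Keep families with at least this many members
#'   (default 6, i.e. "more than five").
#' @param adjust Apply Benjamini-Hochberg correction (default FALSE).
#' @return `data.frame`: `family`, `family_size`, `targeted_in_family`,
#'   `log2fc`, `p` (and `padj` when `adjust`).
#' @export
tfFamilyEnrichment <- function(targetTfIds, familyMap, minFamilySize = 6,
                               adjust = FALSE) {
  targetTfIds <- unique(as.character(targetTfIds))
  if (!all(targetTfIds %in% names(familyMap)))
    stop("familyMap does not cover all target TF ids", call. = FALSE)
  nTargeted <- length(targetTfIds)
  if (nTargeted == 0L) stop("no targeted TFs supplied", call. = FALSE)
  nAll <- length(familyMap)
  fams <- sort(unique(unname(familyMap)))
  rows <- lapply(fams, function(f) {
    famIds <- names(familyMap)[familyMap == f]
    K <- length(famIds)
    if (K < minFamilySize) return(NULL)
    k <- sum(targetTfIds %in% famIds)
    prop_t <- k / nTargeted
    prop_g <- K / nAll
    data.frame(family = f, family_size = K, targeted_in_family = k,
               log2fc = log2(prop_t / prop_g),
               p = hypergeomTest(k, nTargeted, K, nAll))
  })
  out <- do.call(rbind, rows)
  if (isTRUE(adjust) && !is.null(out)) out$padj <- stats::p.adjust(out$p, "BH")
  out
}

#' Categorize genes by promoter Helitron/motif/binding status
#'
#' Assigns each gene to one of four groups based on its 3-kb promoter
#' (upstream of the TSS in gene orientation): (i) carries an RC/Helitron
#' and a binding motif and is bound by a site (a domesticated TE);
#' (ii) Helitron and motif present but not bound; (iii) Helitron without a
#' motif; (iv) no promoter Helitron. Used to compare the expression of
#' TE-flanked genes across categories.
#'
#' @param genes `GRanges` with `gene_id` and `tss`.
#' @param teSet `GRanges` of the relevant TE copies (e.g. RC/Helitrons).
#' @param motifMatches `GRanges` from [scanConsensus()].
#' @param boundSites `GRanges` of binding sites (or [BindingSiteSet-class]).
#' @param promoterSpan Promoter length (default 3000).
#' @return Named character vector gene_id -> category
#'   (`"helitron_motif_bound"`, `"helitron_motif_unbound"`,
#'   `"helitron_no_motif"`, `"no_helitron"`).
#' @export
categorizeFlankingGenes <- function(genes, teSet, motifMatches, boundSites,
                                    promoterSpan = 3000) {
  if (is(boundSites, "BindingSiteSet")) boundSites <- sites(boundSites)
  prom <- promoterUniverse(genes, span = promoterSpan)
  hasTe <- countOverlaps(prom, teSet, ignore.strand = TRUE) > 0L
  hasMotif <- countOverlaps(prom, motifMatches, ignore.strand = TRUE) > 0L
  isBound <- countOverlaps(prom, boundSites, ignore.strand = TRUE) > 0L
  cat_ <- ifelse(!hasTe, "no_helitron",
          ifelse(!hasMotif, "helitron_no_motif",
          ifelse(isBound, "helitron_motif_bound", "helitron_motif_unbound")))
  out <- setNames(cat_, prom$gene_id)
  # genes whose promoter collapsed to nothing (TSS at a chromosome edge)
  missing <- setdiff(as.character(genes$gene_id), names(out))
  c(out, setNames(rep("no_helitron", length(missing)), missing))
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' U is computed with midranks for ties. When both groups have at most 8
#' observations the p-value comes from exact enumeration of all group
#' assignments (valid under ties); otherwise from the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction, as
#' implemented by [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return List: `U` (statistic for `x`), `p`, `medians` (named), and
#'   `method`.
#' @examples
#' compareGroupsMW(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, by exact enumeration
#' @export
compareGroupsMW <- function(x, y,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8L && n2 <= 8L) {
    p <- exactMWP(c(x, y), n1, U, alternative)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation with continuity correction"
  }
  list(U = U, p = p, medians = c(x = median(x), y = median(y)),
       method = method)
}

# exact two-sample MW p by enumerating all C(n, n1) group assignments;
# handles ties because ranks are fixed across assignments
exactMWP <- function(values, n1, Uobs, alternative) {
  r <- rank(values)
  n <- length(values)
  mu <- n1 * (n - n1) / 2
  sets <- combn(n, n1)
  Us <- apply(sets, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  switch(alternative,
    two.sided = mean(abs(Us - mu) >= abs(Uobs - mu) - eps),
    greater = mean(Us >= Uobs - eps),
    less = mean(Us <= Uobs + eps))
}

#' k-means clustering with k-means++ initialization
#'
#' Lloyd's algorithm under the squared-Euclidean objective, initialized
#' with k-means++ seeding and restarted `nInit` times; the restart with
#' the lowest within-cluster sum of squares wins. Deterministic for a
#' fixed seed. Rows containing missing values are dropped and reported.
#'
#' @param x Numeric matrix (observations x features).
#' @param k Number of clusters (>= 2, <= rows).
#' @param seed Integer seed.
#' @param nInit Number of restarts (default 10).
#' @return List: `labels` (per kept row), `centroids`, `withinss` (total),
#'   `dropped` (row indices removed for missing values).
#' @export
kmeansCluster <- function(x, k, seed = 1L, nInit = 10L) {
  x <- as.matrix(x)
  cc <- complete.cases(x)
  dropped <- which(!cc)
  x <- x[cc, , drop = FALSE]
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (nrow(x) < k)
    stop("more clusters than observations", call. = FALSE)
  fit <- withSeed(seed, {
    best <- NULL
    for (i in seq_len(nInit)) {
      centers <- kmeansppInit(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L,
               algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  list(labels = fit$cluster, centroids = fit$centers,
       withinss = fit$tot.withinss, dropped = dropped)
}

# k-means++ seeding: iteratively sample centers proportional to squared
# distance from the nearest chosen center
kmeansppInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  # jitter exact duplicates minimally so stats::kmeans accepts the centers
  if (anyDuplicated(centers))
    centers <- centers + matrix(runif(length(centers), 0, 1e-9),
                                nrow = k)
  centers
}

#' Average endosperm expression over sub-regions
#'
#' Pre-processing helper for expression tables holding log2 fold-changes
#' of several endosperm sub-regions (e.g. micropylar, peripheral and
#' chalazal endosperm): returns their per-gene mean as the single
#' endosperm value used in group comparisons.
#'
#' @param exprTable `data.frame` with a gene id column and one numeric
#'   column per sub-region.
#' @param idCol Name of the gene id column (default `"gene_id"`).
#' @return `data.frame` with `gene_id` and `endosperm_log2fc`.
#' @export
averageEndospermExpression <- function(exprTable, idCol = "gene_id") {
  stopifnot(idCol %in% names(exprTable))
  num <- vapply(exprTable, is.numeric, TRUE)
  num[idCol] <- FALSE
  data.frame(gene_id = exprTable[[idCol]],
             endosperm_log2fc = rowMeans(exprTable[, num, drop = FALSE]))
}
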