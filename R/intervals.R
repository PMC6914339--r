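#' Enumerate overlapping interval pairs
#'
#' Reports every pair of intervals from `a` and `b` that share at least
#' `minOverlap` bases. Intervals that merely touch (half-open adjacency in
#' BED terms) do not overlap.
#'
#' @param a,b `GRanges` objects.
#' @param minOverlap Minimum shared bases for a pair to be reported (>= 1).
#' @return A `data.frame` with columns `queryHits`, `subjectHits` (indices
#'   into `a` and `b`) and `overlap` (shared bases).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))
#' intersectPairs(a, b)
#' @export
intersectPairs <- function(a, b, minOverlap = 1L) {
  assertScalarNumber(minOverlap, "minOverlap", min = 1)
  hits <- findOverlaps(a, b, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  ov <- pmin(end(a)[qh], end(b)[sh]) - pmax(start(a)[qh], start(b)[sh]) + 1L
  data.frame(queryHits = qh, subjectHits = sh, overlap = ov)
}

#' Fraction of query intervals overlapping a subject set
#'
#' The statistic behind TE-overlap enrichment: the proportion of query
#' intervals (e.g. binding sites) that share at least one base with any
#' subject interval (e.g. the copies of a TE superfamily).
#'
#' @param query Non-empty `GRanges`.
#' @param subject `GRanges` (may be empty, giving 0).
#' @return A single number in \[0, 1\].
#' @export
overlapFraction <- function(query, subject) {
  if (length(query) == 0L)
    stop("overlap fraction undefined for an empty query set", call. = FALSE)
  if (length(subject) == 0L) return(0)
  sum(countOverlaps(query, subject, ignore.strand = TRUE) > 0L) / length(query)
}
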