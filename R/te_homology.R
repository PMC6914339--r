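#' Alignment scoring scheme for TE homology detection
#'
#' BLASTN-style nucleotide scoring: match +2, mismatch -3, affine gap
#' penalties with existence cost 5 and extension cost 2 (a gap of length L
#' costs 5 + 2L). `N` is scored as a mismatch against every base.
#'
#' @param match,mismatch Substitution scores.
#' @param gapOpen,gapExtend Positive gap costs.
#' @return A list of class `"AlignmentScoring"`.
#' @export
alignmentScoring <- function(match = 2, mismatch = -3, gapOpen = 5,
                             gapExtend = 2) {
  stopifnot(match > 0, mismatch < 0, gapOpen > 0, gapExtend > 0)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "AlignmentScoring")
}

substitutionMatrixN <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- scoring$match
  m["N", "N"] <- scoring$mismatch  # N never counts as a match
  m
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine gap penalties, replacing
#' the seeded heuristic of BLAST with the exhaustive optimum (which can
#' only find more homology at desk scale; the homology thresholds, not the
#' seeding, carry the biology). Percent identity is computed over all
#' alignment columns, counting gap columns as non-identical.
#'
#' @param a,b Non-empty DNA sequences (character or `DNAString`).
#' @param scoring An [alignmentScoring()] scheme.
#' @return A list of class `"LocalAlignment"`: `score`, `length` (alignment
#'   columns), `identity` (percent), `startA`, `endA`, `startB`, `endB`
#'   (1-based spans on each input), `alignedA`, `alignedB`.
#' @examples
#' localAlign("ACGTACGTACGT", "ACGTACGTACGT")$score  # 24
#' @export
localAlign <- function(a, b, scoring = alignmentScoring()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  pa <- pairwiseAlignment(DNAString(a), DNAString(b),
                          substitutionMatrix = substitutionMatrixN(scoring),
                          gapOpening = scoring$gapOpen,
                          gapExtension = scoring$gapExtend,
                          type = "local")
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  len <- nchar(alnA)
  ident <- if (len > 0L) 100 * nmatch(pa) / len else 0
  structure(list(score = score(pa), length = len, identity = ident,
                 startA = start(pattern(pa)), endA = end(pattern(pa)),
                 startB = start(subject(pa)), endB = end(subject(pa)),
                 alignedA = alnA, alignedB = alnB),
            class = "LocalAlignment")
}

#' Decide whether an alignment supports homology
#'
#' Intra-genome rule (motif-carrying TE copies of one genome): the aligned
#' span on the reference sequence must cover at least 9 of the 10 motif
#' bases, the alignment must be longer than 30 columns, and identity must
#' exceed 70 percent (all boundaries strict where stated). Cross-species
#' rule (reference TE vs an orthologous promoter): the aligned span on the
#' reference must exceed 100 nt with identity above 60 percent.
#'
#' @param aln A `"LocalAlignment"` (sequence A is the reference).
#' @param motifSpan Integer `c(start, end)` of the motif on the reference
#'   sequence (1-based, closed); required for the intra-genome profile.
#' @param profile `"intra_genome"` or `"cross_species"`.
#' @param minMotifCoverage Required covered motif bases (default 9).
#' @return Logical verdict, with attribute `stats` (named numeric).
#' @export
pairHomology <- function(aln, motifSpan = NULL,
                         profile = c("intra_genome", "cross_species"),
                         minMotifCoverage = 9) {
  profile <- match.arg(profile)
  spanA <- aln$endA - aln$startA + 1
  if (profile == "intra_genome") {
    if (is.null(motifSpan))
      stop("motifSpan is required for the intra-genome profile",
           call. = FALSE)
    cov <- max(0, min(aln$endA, motifSpan[2L]) -
                  max(aln$startA, motifSpan[1L]) + 1)
    verdict <- cov >= minMotifCoverage && aln$length > 30 &&
      aln$identity > 70
    stats <- c(motif_coverage = cov, length = aln$length,
               identity = aln$identity)
  } else {
    verdict <- spanA > 100 && aln$identity > 60
    stats <- c(ref_span = spanA, identity = aln$identity)
  }
  structure(verdict, stats = stats)
}

#' Merge homologous pairs into clusters
#'
#' Connected components of the homology graph: any two elements joined by
#' a chain of pairwise homologies land in one cluster; elements with no
#' homologous partner are singletons. Cluster ids are deterministic (the
#' lexicographically smallest member names the cluster).
#'
#' @param elements Character vector of element ids.
#' @param pairs Two-column matrix or data.frame of homologous id pairs
#'   (may have zero rows).
#' @return `data.frame` with `element` and `cluster` columns.
#' @export
clusterPairs <- function(elements, pairs) {
  elements <- as.character(elements)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    memb <- setNames(seq_along(elements), elements)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    pm <- cbind(as.character(pairs[[1L]]), as.character(pairs[[2L]]))
    unknown <- setdiff(c(pm), elements)
    if (length(unknown))
      stop("pair references unknown element(s): ",
           paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
    g <- igraph::graph_from_data_frame(as.data.frame(pm), directed = FALSE,
                                       vertices = data.frame(name = elements))
    memb <- igraph::components(g)$membership
  }
  cluster <- vapply(split(names(memb), memb),
                    function(ms) min(ms), "")[as.character(memb)]
  out <- data.frame(element = names(memb), cluster = unname(cluster))
  out[order(out$cluster, out$element), , drop = FALSE]
}

#' All-pairs homology clustering of motif-carrying sequences
#'
#' Convenience wrapper: aligns every sequence pair, applies the
#' intra-genome homology rule anchored on each pair's reference motif, and
#' merges the accepted pairs into clusters.
#'
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @param motifSpans Named list of `c(start, end)` motif positions, one per
#'   sequence.
#' @param scoring An [alignmentScoring()] scheme.
#' @return A list with `pairs` (data.frame of all evaluated pairs: a, b,
#'   score, length, identity, motif_coverage, homologous) and `clusters`
#'   (output of [clusterPairs()]).
#' @export
homologyClusters <- function(seqs, motifSpans,
                             scoring = alignmentScoring()) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  ids <- names(seqs)
  stopifnot(!is.null(ids), all(ids %in% names(motifSpans)))
  cmb <- if (length(ids) >= 2L) combn(ids, 2L) else
    matrix(character(), nrow = 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1L, j]; b <- cmb[2L, j]
    aln <- localAlign(seqs[[a]], seqs[[b]], scoring)
    verdict <- pairHomology(aln, motifSpans[[a]], "intra_genome")
    st <- attr(verdict, "stats")
    data.frame(a = a, b = b, score = aln$score, length = aln$length,
               identity = aln$identity,
               motif_coverage = unname(st["motif_coverage"]),
               homologous = as.logical(verdict))
  })
  pairsDf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), score = numeric(),
               length = numeric(), identity = numeric(),
               motif_coverage = numeric(), homologous = logical())
  hom <- pairsDf[pairsDf$homologous, c("a", "b"), drop = FALSE]
  list(pairs = pairsDf, clusters = clusterPairs(ids, hom))
}
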