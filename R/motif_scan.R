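#' Describe a consensus binding motif
#'
#' The default is the canonical CArG-box `CCWWWWWWGG` (CC(A/T)6GG), the
#' signature motif of MADS-box transcription-factor binding sites. Any
#' IUPAC consensus of length >= 4 is accepted.
#'
#' @param consensus IUPAC consensus string.
#' @param id Motif label.
#' @return A list of class `"Motif"` with elements `id`, `consensus`,
#'   `length`.
#' @export
motif <- function(consensus = "CCWWWWWWGG", id = "CArG") {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4L)
    stop("consensus must be at least 4 bases", call. = FALSE)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", consensus))
    stop("consensus contains invalid IUPAC codes", call. = FALSE)
  structure(list(id = id, consensus = consensus,
                 length = nchar(consensus)), class = "Motif")
}

# IUPAC code -> base set, used by the Hamming classifier
iupacSets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Scan sequences for motif matches on both strands
#'
#' Finds every position whose forward or reverse-complement window matches
#' the consensus with at most one substitution, classifying each hit as
#' `perfect` (0 substitutions from the consensus-defined set) or
#' `nearly_perfect` (minimal Hamming distance exactly 1, i.e. one
#' substitution away from some perfect sequence). Windows containing `N`
#' never match. For palindromic consensi (the CArG-box class is its own
#' reverse complement) a single genomic occurrence is reported once, on the
#' `+` strand.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param m A [motif()] object.
#' @param nearlyPerfect Also report nearly-perfect matches (default TRUE).
#' @return `GRanges` with `strand`, `matched` (the genomic 10-mer) and
#'   `class` metadata columns.
#' @export
scanConsensus <- function(seqs, m = motif(), nearlyPerfect = TRUE) {
  if (is.character(seqs)) seqs <- readDNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pat <- DNAString(m$consensus)
  rcpat <- reverseComplement(pat)
  maxmm <- if (nearlyPerfect) 1L else 0L
  hits <- list()
  for (strandPat in list(list(p = pat, s = "+"), list(p = rcpat, s = "-"))) {
    mi <- vmatchPattern(strandPat$p, seqs, max.mismatch = maxmm,
                        fixed = "subject")
    for (sq in names(seqs)) {
      v <- mi[[sq]]
      if (length(v) == 0L) next
      st <- start(v)
      keep <- st >= 1L & end(v) <= length(seqs[[sq]])
      st <- st[keep]
      if (length(st) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = sq, start = st, end = st + m$length - 1L,
        strand = strandPat$s)
    }
  }
  if (length(hits) == 0L)
    return(GRanges(matched = character(), class = character()))
  df <- do.call(rbind, hits)
  # deduplicate identical coordinates across strands (palindromic hits):
  # keep the + record
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  df <- df[!duplicated(df[, c("chrom", "start")]), , drop = FALSE]
  tenmer <- mapply(function(chr, s) {
    as.character(Biostrings::subseq(seqs[[chr]], s, s + m$length - 1L))
  }, df$chrom, df$start)
  cls <- vapply(tenmer, function(w) {
    d <- min(hammingToConsensus(w, m$consensus),
             hammingToConsensus(revcompString(w), m$consensus))
    if (d == 0L) "perfect" else if (d == 1L) "nearly_perfect" else "none"
  }, "")
  keep <- cls != "none" & !grepl("N", tenmer, fixed = TRUE)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    return(GRanges(matched = character(), class = character()))
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  gr$matched <- unname(tenmer[keep])
  gr$class <- unname(cls[keep])
  sortIntervals(gr)
}

# substitutions needed to turn `w` into some member of the consensus set
hammingToConsensus <- function(w, consensus) {
  sets <- iupacSets()
  wb <- strsplit(w, "")[[1L]]
  cb <- strsplit(consensus, "")[[1L]]
  if (length(wb) != length(cb))
    stop("sequence length does not match motif length", call. = FALSE)
  sum(vapply(seq_along(wb), function(i) !(wb[i] %in% sets[[cb[i]]]), TRUE))
}

revcompString <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

#' Classify a k-mer against a consensus motif
#'
#' `perfect` when the k-mer belongs to the consensus-defined sequence set,
#' `nearly_perfect` when one substitution suffices to reach it (minimal
#' Hamming distance to the set, taken over both strands, is exactly 1),
#' `none` otherwise. `N` counts as a mismatch at its position.
#'
#' @param kmer A string the same length as the motif.
#' @param m A [motif()] object.
#' @return One of `"perfect"`, `"nearly_perfect"`, `"none"`.
#' @examples
#' classifyMatch("CCAAAAAAGG")  # perfect
#' classifyMatch("CCAAAAAAGT")  # nearly_perfect
#' @export
classifyMatch <- function(kmer, m = motif()) {
  kmer <- toupper(kmer)
  if (nchar(kmer) != m$length)
    stop("k-mer length (", nchar(kmer), ") does not match motif length (",
         m$length, ")", call. = FALSE)
  d <- min(hammingToConsensus(kmer, m$consensus),
           hammingToConsensus(revcompString(kmer), m$consensus))
  if (d == 0L) "perfect" else if (d == 1L) "nearly_perfect" else "none"
}

#' Motif density per genomic region class with pairwise chi-square tests
#'
#' Density is the number of motif occurrences falling inside a region class
#' divided by the class's total length in bases. Region classes are
#' compared pairwise with a 2x2 chi-square test of independence on the
#' proportion of bases that are motif bases versus non-motif bases.
#'
#' @param regionsByClass Named list of `GRanges`, one element per region
#'   class (e.g. TE superfamilies); intervals within a class must not
#'   overlap.
#' @param matches Motif matches from [scanConsensus()].
#' @param motifLength Bases per occurrence (default taken from matches).
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return A list with `density` (data.frame: class, n_matches, bases,
#'   density, motif_base_fraction) and `tests` (data.frame: classA, classB,
#'   chisq, p).
#' @export
motifDensity <- function(regionsByClass, matches, motifLength = NULL,
                         yates = FALSE) {
  stopifnot(is.list(regionsByClass), !is.null(names(regionsByClass)))
  if (is.null(motifLength))
    motifLength <- if (length(matches)) width(matches)[1L] else 10L
  cls <- names(regionsByClass)
  dens <- do.call(rbind, lapply(cls, function(cl) {
    gr <- regionsByClass[[cl]]
    bases <- sum(width(gr))
    if (bases == 0L)
      stop("region class '", cl, "' has zero total length", call. = FALSE)
    # occurrences are assigned by their start base, so densities are
    # exactly invariant under splitting a region into adjacent pieces
    anchors <- GRanges(seqnames(matches),
                       IRanges(start(matches), width = 1L))
    nm <- sum(countOverlaps(anchors, gr, ignore.strand = TRUE) > 0L)
    data.frame(class = cl, n_matches = nm, bases = bases,
               density = nm / bases,
               motif_base_fraction = nm * motifLength / bases)
  }))
  tests <- NULL
  if (length(cls) >= 2L) {
    pairs <- combn(cls, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- dens[dens$class == pairs[1L, j], ]
      b <- dens[dens$class == pairs[2L, j], ]
      tab <- rbind(c(a$n_matches * motifLength,
                     a$bases - a$n_matches * motifLength),
                   c(b$n_matches * motifLength,
                     b$bases - b$n_matches * motifLength))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab, correct = yates))
        data.frame(classA = pairs[1L, j], classB = pairs[2L, j],
                   chisq = unname(ct$statistic), p = ct$p.value)
      } else {
        data.frame(classA = pairs[1L, j], classB = pairs[2L, j],
                   chisq = 0, p = 1)
      }
    }))
  }
  list(density = dens, tests = tests)
}
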