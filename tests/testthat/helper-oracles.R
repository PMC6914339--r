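# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (quadratic
# loops, full DP matrices, exhaustive enumeration) so they share no code
# path with the functions they check.

library(GenomicRanges)
library(Biostrings)

# all-vs-all interval pair enumeration (1-based closed coordinates)
oracleIntersect <- function(a, b, minOverlap = 1) {
  rows <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1
    if (ov >= minOverlap)
      rows[[length(rows) + 1L]] <- c(i, j, ov)
  }
  if (!length(rows))
    return(data.frame(queryHits = integer(), subjectHits = integer(),
                      overlap = integer()))
  m <- do.call(rbind, rows)
  data.frame(queryHits = m[, 1], subjectHits = m[, 2], overlap = m[, 3])
}

randomIntervalSet <- function(n, chroms = c("chr1", "chr2"), span = 5000,
                              maxLen = 120) {
  st <- sample.int(span, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(st, width = w))
}

# naive affine-gap Smith-Waterman: three full DP matrices, gap of length
# L costs open + ext * L
oracleLocalAlignScore <- function(a, b, match = 2, mismatch = -3,
                                  open = 5, ext = 2) {
  A <- strsplit(toupper(a), "")[[1L]]
  B <- strsplit(toupper(b), "")[[1L]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)       # alignment ends in a substitution
  X <- matrix(-Inf, n + 1, m + 1)    # gap in B (consume A)
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in A (consume B)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                   Y[i - 1, j - 1]) + s
    if (M[i, j] < 0) M[i, j] <- 0   # local alignment restarts
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# enumerate the 2^6 perfect CArG sequences once
perfectCargSet <- function() {
  w <- expand.grid(rep(list(c("A", "T")), 6), stringsAsFactors = FALSE)
  apply(w, 1, function(x) paste0("CC", paste(x, collapse = ""), "GG"))
}

# minimal Hamming distance of a 10-mer to the perfect set, either strand
oracleCargDistance <- function(tenmer, perfectSet = perfectCargSet()) {
  rc <- as.character(reverseComplement(DNAString(tenmer)))
  dist1 <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  min(vapply(perfectSet, dist1, 0L, x = tenmer),
      vapply(perfectSet, dist1, 0L, x = rc))
}

# sliding-window scan of one sequence; returns every window with minimal
# Hamming distance 0 (perfect) or 1 (nearly perfect) to the consensus
# set on either strand, N windows excluded. Positions are independent,
# so the distance to the set is the count of disallowed bases per
# position (spot-checked against the explicit 2^6 enumeration elsewhere).
oracleScan <- function(seqChar, k = 10) {
  W <- c("A", "T")
  allowedF <- list("C", "C", W, W, W, W, W, W, "G", "G")
  # reverse complement of the consensus, position by position
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  allowedR <- rev(lapply(allowedF, function(s) unname(comp[s])))
  ch <- strsplit(seqChar, "")[[1L]]
  nwin <- length(ch) - k + 1
  dF <- integer(nwin); dR <- integer(nwin); hasN <- logical(nwin)
  for (j in seq_len(k)) {
    base <- ch[j:(j + nwin - 1)]
    dF <- dF + !(base %in% allowedF[[j]])
    dR <- dR + !(base %in% allowedR[[j]])
    hasN <- hasN | base == "N"
  }
  d <- pmin(dF, dR)
  sel <- which(d <= 1 & !hasN)
  if (!length(sel)) return(NULL)
  data.frame(start = sel, end = sel + k - 1,
             matched = vapply(sel, function(s)
               paste(ch[s:(s + k - 1)], collapse = ""), ""),
             class = ifelse(d[sel] == 0, "perfect", "nearly_perfect"))
}

# hypergeometric upper-tail p by summing closed-form terms
oracleHyperP <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracleMWP <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r <- rank(vals)
  mu <- n1 * length(y) / 2
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(length(vals), n1)
  Us <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

# transitive-closure clustering oracle (repeated relabelling to fixpoint)
oracleComponents <- function(elements, pairs) {
  lab <- setNames(seq_along(elements), elements)
  repeat {
    changed <- FALSE
    for (r in seq_len(NROW(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      m <- min(lab[[a]], lab[[b]])
      if (lab[[a]] != m || lab[[b]] != m) {
        lab[lab %in% c(lab[[a]], lab[[b]])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# mutate a sequence at a fixed per-base substitution rate, sparing a span
mutateSequence <- function(seqChar, rate, spareStart = NA, spareEnd = NA) {
  ch <- strsplit(seqChar, "")[[1L]]
  mut <- runif(length(ch)) < rate
  if (!is.na(spareStart)) mut[spareStart:spareEnd] <- FALSE
  bases <- c("A", "C", "G", "T")
  ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(bases, b), 1), "")
  paste(ch, collapse = "")
}
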