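# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic ordering used for every emitted interval set:
# chrom (lexicographic), start, end, then name.
sortIntervals <- function(gr) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
  ord <- order(as.character(seqnames(gr)), start(gr), end(gr), nm,
               method = "radix")
  gr[ord]
}

# midpoint (1-based coordinate) of each range; left-of-centre for even widths
intervalMid <- function(gr) {
  floor((start(gr) + end(gr)) / 2)
}

assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min),
         call. = FALSE)
  invisible(x)
}
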