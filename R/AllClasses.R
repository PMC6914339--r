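#' BindingSiteSet: replicate-supported binding sites
#'
#' Container for the regions supported by ChIP peaks in both biological
#' replicates ("binding sites"), together with the contributing replicate
#' peak sets and the per-replicate reproducibility fractions (the fraction
#' of each replicate's peaks that overlap a peak of the other replicate).
#'
#' @slot sites `GRanges` of merged common-peak regions, mutually
#'   non-overlapping, each annotated with the indices of the contributing
#'   replicate-1 and replicate-2 peaks (`rep1_peaks`, `rep2_peaks`,
#'   comma-separated).
#' @slot rep1,rep2 The input peak `GRanges` for each replicate.
#' @slot reproducibility Named numeric of length 2 (`rep1`, `rep2`).
#'
#' @seealso [commonPeaks()] which constructs these objects.
#' @export
setClass("BindingSiteSet",
  representation(sites = "GRanges", rep1 = "GRanges", rep2 = "GRanges",
                 reproducibility = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- object@sites
    if (length(s) > 1L) {
      self <- findOverlaps(s, s, ignore.strand = TRUE)
      if (any(queryHits(self) != subjectHits(self)))
        msg <- c(msg, "sites must be mutually non-overlapping")
    }
    if (length(s) > 0L) {
      if (!all(countOverlaps(s, object@rep1, ignore.strand = TRUE) > 0L) ||
          !all(countOverlaps(s, object@rep2, ignore.strand = TRUE) > 0L))
        msg <- c(msg, "every site must overlap a peak from each replicate")
    }
    if (length(object@reproducibility) != 2L)
      msg <- c(msg, "reproducibility must have length 2")
    if (length(msg)) msg else TRUE
  })

#' @describeIn BindingSiteSet-class The merged binding-site regions.
#' @param x,object A `BindingSiteSet`.
#' @aliases sites
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname BindingSiteSet-class
#' @export
setMethod("sites", "BindingSiteSet", function(x) x@sites)

#' @describeIn BindingSiteSet-class Per-replicate fraction of peaks
#'   overlapping the other replicate.
#' @aliases reproducibility
#' @export
setGeneric("reproducibility", function(x) standardGeneric("reproducibility"))

#' @rdname BindingSiteSet-class
#' @export
setMethod("reproducibility", "BindingSiteSet", function(x) x@reproducibility)

#' @rdname BindingSiteSet-class
#' @export
setMethod("length", "BindingSiteSet", function(x) length(x@sites))

setMethod("show", "BindingSiteSet", function(object) {
  cat("BindingSiteSet with", length(object@sites), "binding sites\n")
  cat(sprintf("  replicate peaks: %d (rep1), %d (rep2)\n",
              length(object@rep1), length(object@rep2)))
  cat(sprintf("  reproducibility: %.1f%% (rep1), %.1f%% (rep2)\n",
              100 * object@reproducibility[[1L]],
              100 * object@reproducibility[[2L]]))
})
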