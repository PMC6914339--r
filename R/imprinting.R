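#' Per-gene parental expression ratios
#'
#' The parental expression ratio of a gene is the number of maternally
#' derived reads divided by the total (maternal + paternal) reads.
#' Ratios are computed per replicate, replicates with fewer than
#' `minInformative` total reads are discarded, and the surviving
#' replicate ratios are averaged per gene and cross.
#'
#' @param records `data.frame` with columns `gene_id`, `cross`,
#'   `replicate`, `maternal`, `paternal`.
#' @param minInformative Minimum total reads for a replicate to count
#'   (default 10).
#' @return `data.frame`: `gene_id`, `cross`, `maternal_fraction` (NA when
#'   no replicate survives), `n_replicates`, `insufficient_data`.
#' @examples
#' rec <- data.frame(gene_id = "g1", cross = "2x", replicate = 1:2,
#'                   maternal = c(8, 6), paternal = c(2, 4))
#' parentalRatio(rec)$maternal_fraction  # (0.8 + 0.6) / 2
#' @export
parentalRatio <- function(records, minInformative = 10) {
  need <- c("gene_id", "cross", "replicate", "maternal", "paternal")
  stopifnot(all(need %in% names(records)))
  if (any(records$maternal < 0) || any(records$paternal < 0))
    stop("read counts must be non-negative", call. = FALSE)
  tot <- records$maternal + records$paternal
  frac <- ifelse(tot > 0, records$maternal / tot, NA_real_)
  ok <- tot >= minInformative & !is.na(frac)
  key <- paste(records$gene_id, records$cross, sep = "\r")
  mf <- tapply(ifelse(ok, frac, NA_real_), key, mean, na.rm = TRUE)
  nr <- tapply(ok, key, sum)
  ids <- do.call(rbind, strsplit(names(mf), "\r", fixed = TRUE))
  out <- data.frame(gene_id = ids[, 1L], cross = ids[, 2L],
                    maternal_fraction = ifelse(nr > 0, as.numeric(mf),
                                               NA_real_),
                    n_replicates = as.integer(nr))
  out$insufficient_data <- out$n_replicates == 0L
  rownames(out) <- NULL
  out[order(out$gene_id, out$cross), , drop = FALSE]
}

#' Ploidy-aware MEG/PEG classification thresholds
#'
#' The expected maternal:total read ratio of a biallelic gene is 2:3 in
#' 2x seeds (two maternal genomes, one paternal) and 2:4 in 3x
#' paternal-excess seeds. Imprinting thresholds are a `fold`-fold
#' deviation of this expectation applied on the maternal:paternal odds
#' scale: with expected odds `w`, a MEG requires odds >= `fold * w`
#' (fraction >= `fold*w/(fold*w + 1)`) and a PEG odds <= `w / fold`.
#' The odds scale is the only interpretation that keeps both thresholds
#' inside (0, 1) for any expectation and treats both directions
#' symmetrically.
#'
#' @param cross `"2x"` or `"3x_paternal_excess"`.
#' @param fold Fold deviation (default 4).
#' @return List of class `"ImprintingThresholds"`: `cross`,
#'   `expected_fraction`, `fold`, `meg_min_fraction`, `peg_max_fraction`.
#' @examples
#' imprintingThresholds("2x")  # MEG >= 8/9, PEG <= 1/3
#' imprintingThresholds("3x_paternal_excess")  # MEG >= 4/5, PEG <= 1/5
#' @export
imprintingThresholds <- function(cross, fold = 4) {
  assertScalarNumber(fold, "fold", min = 1)
  omega <- crossOdds(cross)
  structure(list(cross = cross,
                 expected_fraction = omega / (omega + 1),
                 fold = fold,
                 meg_min_fraction = (fold * omega) / (fold * omega + 1),
                 peg_max_fraction = (omega / fold) / (omega / fold + 1)),
            class = "ImprintingThresholds")
}

#' @export
print.ImprintingThresholds <- function(x, ...) {
  cat(sprintf(
    "ImprintingThresholds [%s]: expected %.3f, MEG >= %.4f, PEG <= %.4f\n",
    x$cross, x$expected_fraction, x$meg_min_fraction,
    x$peg_max_fraction))
  invisible(x)
}

#' Classify genes as MEG, PEG or biallelic
#'
#' Applies the ploidy-aware thresholds to per-gene maternal fractions:
#' MEG when the fraction is at or above the MEG minimum, PEG when at or
#' below the PEG maximum, biallelic otherwise (boundaries inclusive).
#' When both crosses are present, a 2x-versus-3x cross-tabulation of the
#' labels is attached — the "is imprinting maintained under paternal
#' excess?" readout.
#'
#' @param fractions Output of [parentalRatio()] (or a data.frame with
#'   `gene_id`, `cross`, `maternal_fraction`).
#' @param fold Fold deviation for the thresholds (default 4).
#' @return `data.frame`: `gene_id`, `cross`, `maternal_fraction`,
#'   `label` in MEG/PEG/biallelic/insufficient_data; attribute
#'   `crossTable` (2x vs 3x label contingency) when both crosses occur.
#' @export
classifyImprinting <- function(fractions, fold = 4) {
  f <- fractions$maternal_fraction
  if (any(!is.na(f) & (f < 0 | f > 1)))
    stop("maternal fractions must lie in [0, 1]", call. = FALSE)
  labs <- character(nrow(fractions))
  for (cross in unique(fractions$cross)) {
    th <- imprintingThresholds(cross, fold)
    i <- fractions$cross == cross
    labs[i] <- ifelse(is.na(f[i]), "insufficient_data",
               ifelse(f[i] >= th$meg_min_fraction, "MEG",
               ifelse(f[i] <= th$peg_max_fraction, "PEG", "biallelic")))
  }
  out <- data.frame(gene_id = fractions$gene_id, cross = fractions$cross,
                    maternal_fraction = f, label = labs)
  crosses <- unique(out$cross)
  if (all(c("2x", "3x_paternal_excess") %in% crosses)) {
    a <- out[out$cross == "2x", c("gene_id", "label")]
    b <- out[out$cross == "3x_paternal_excess", c("gene_id", "label")]
    mg <- merge(a, b, by = "gene_id", suffixes = c("_2x", "_3x"))
    attr(out, "crossTable") <- table(`2x` = mg$label_2x,
                                     `3x` = mg$label_3x)
  }
  out
}
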