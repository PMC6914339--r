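#' Read genomic intervals from BED or GFF3
#'
#' Reads a BED3/BED6 or GFF3 file into a [GenomicRanges::GRanges]. BED input
#' (0-based, half-open) and GFF3 input (1-based, closed) are both converted
#' to the 1-based closed convention GRanges uses, so downstream overlap
#' arithmetic never mixes coordinate systems. Malformed lines (non-integer
#' coordinates, empty intervals after conversion) raise an error naming the
#' offending line.
#'
#' @param path Path to the file.
#' @param format Either `"bed"` or `"gff3"`.
#' @return A `GRanges`, sorted by (chrom, start, end, name). BED columns 4-6
#'   become `name`, `score`, strand; GFF3 attributes are kept as metadata
#'   columns (`source`, `type`, `attributes`, and `ID`/`Name` when present).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpeak1", bed)
#' parseIntervals(bed, "bed")
#' @export
parseIntervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(tolower(format), c("bed", "gff3"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "bed") parseBed(path) else parseGff3(path)
}

parseBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 fields", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop("BED parse error at line ", idx[bad[1L]],
         ": non-integer coordinates", call. = FALSE)
  bad <- which(s < 0 | s >= e)
  if (length(bad))
    stop("BED parse error at line ", idx[bad[1L]],
         ": start must satisfy 0 <= start < end", call. = FALSE)
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", "")
  score <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else ".", "")
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start = s + 1L, end = e), strand = strand)
  gr$name <- name
  sc <- suppressWarnings(as.numeric(score))
  if (!all(is.na(sc))) gr$score <- sc
  sortIntervals(gr)
}

parseGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- as(gr, "GRanges")
  if (!is.null(gr$ID)) gr$name <- as.character(gr$ID)
  sortIntervals(gr)
}

#' Write intervals to BED
#'
#' Writes a `GRanges` as BED6 (or BED3 if it carries no names), converting
#' from the internal 1-based closed convention to BED's 0-based half-open
#' coordinates. Output rows follow the deterministic (chrom, start, end,
#' name) sort so that reruns are byte-identical.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param feature Optional character vector written in the BED name column
#'   (e.g. TE superfamily labels); defaults to `gr$name`.
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path, feature = NULL) {
  gr <- sortIntervals(gr)
  nm <- feature
  if (is.null(nm)) nm <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  if (is.null(nm)) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
  } else {
    score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = nm, score = score, strand = str)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' @param genes A `GRanges` with a `gene_id` metadata column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeGff3 <- function(genes, path) {
  genes <- sortIntervals(genes)
  str <- as.character(strand(genes))
  str[str == "*"] <- "."
  df <- data.frame(seqid = as.character(seqnames(genes)),
                   source = "imprintTE", type = "gene",
                   start = start(genes), end = end(genes),
                   score = ".", strand = str, phase = ".",
                   attributes = paste0("ID=", genes$gene_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts `type == "gene"` records and derives the transcription start
#' site from the strand: `start` for `+` genes, `end` for `-` genes.
#'
#' @param path GFF3 file.
#' @return A `GRanges` with `gene_id` and `tss` metadata columns.
#' @export
readGenes <- function(path) {
  gr <- parseGff3(path)
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) == "gene"]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else gr$name
  gr$gene_id <- id
  gr$tss <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  sortIntervals(gr)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return A `GRanges` with a numeric `score` column.
#' @export
readBedGraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "score"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  gr$score <- df$score
  sort(gr)
}

#' Write a signal track as bedGraph
#'
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(track, path) {
  track <- sort(track)
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = end(track),
                   score = track$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# deterministic TSV writer used by every stage output
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
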