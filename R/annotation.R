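#' Load a BED file as a merged interval set
#'
#' Reads a 3+ column BED file (0-based, half-open intervals) and returns a
#' merged, sorted `GRanges` (1-based, closed — the usual in-memory
#' convention; the coordinate conversion happens here and in [writeBed()]
#' only). Overlapping or abutting input intervals are merged.
#'
#' @param path BED file path. Track/browser/comment lines are skipped.
#' @return A merged `GRanges`.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t300"), bed)
#' loadBed(bed)  # one interval chr1:101-300
loadBed <- function(path) {
  if (!file.exists(path))
    .stopFatal("autozyg_io_error", paste("BED not found:", path))
  raw <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  lineNo <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0L) return(GenomicRanges::GRanges())
  f <- strsplit(raw, "\t")
  nf <- lengths(f)
  if (any(nf < 3L))
    .stopFatal("autozyg_bed_error",
               sprintf("BED line %d: fewer than 3 columns",
                       lineNo[which(nf < 3L)[1L]]))
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    .stopFatal("autozyg_bed_error",
               sprintf("BED line %d: non-numeric coordinates",
                       lineNo[which(bad)[1L]]))
  if (any(start0 >= end0))
    .stopFatal("autozyg_bed_error",
               sprintf("BED line %d: start >= end",
                       lineNo[which(start0 >= end0)[1L]]))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0))
  .sortGR(GenomicRanges::reduce(gr))
}

#' Write intervals as a BED3 file
#'
#' Converts 1-based closed intervals back to the BED 0-based half-open
#' convention.
#'
#' @param gr a `GRanges` (or [RohSet], whose ranges are taken).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  gr <- rohRanges(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a two-column chromosome-length table
#'
#' @param path TSV with columns: chromosome name, length in bp. Comment
#'   lines (`#`) are skipped.
#' @return Named numeric vector of lengths.
#' @export
loadChromLengths <- function(path) {
  if (!file.exists(path))
    .stopFatal("autozyg_io_error", paste("length table not found:", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          colClasses = c("character", "numeric"))
  if (ncol(df) < 2L)
    .stopFatal("autozyg_io_error", "length table needs 2 columns (name, bp)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Assemble genome annotation resources
#'
#' Bundles the interval resources the detector and the evaluation need:
#' repeat regions (variants inside are removed before detection), assembly
#' gap regions (subtracted in performance evaluation), and chromosome
#' lengths (bounding boundary extension). Each argument may be a `GRanges`,
#' a BED / TSV file path, or omitted.
#'
#' @param repeats repeat regions: `GRanges` or BED path.
#' @param gaps assembly gaps (centromeres, telomeres, short arms,
#'   heterochromatin): `GRanges` or BED path.
#' @param chromLengths named numeric vector or two-column TSV path.
#' @return A [GenomeAnnotation] object.
#' @export
genomeAnnotation <- function(repeats = NULL, gaps = NULL,
                             chromLengths = NULL) {
  asGr <- function(x) {
    if (is.null(x)) return(GenomicRanges::GRanges())
    if (is.character(x)) return(loadBed(x))
    GenomicRanges::reduce(x)
  }
  if (is.character(chromLengths)) chromLengths <- loadChromLengths(chromLengths)
  if (is.null(chromLengths)) chromLengths <- stats::setNames(numeric(0), character(0))
  new("GenomeAnnotation", repeats = asGr(repeats), gaps = asGr(gaps),
      chromLengths = chromLengths)
}

#' Point membership in an interval set
#'
#' Tests whether 1-based positions fall inside an interval set. Unknown
#' chromosomes return `FALSE`. Chromosome naming styles ("chr1" vs "1")
#' are reconciled automatically.
#'
#' @param set a `GRanges` interval set (e.g. from [loadBed()]).
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return Logical vector.
#' @export
#' @examples
#' set <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
#' containsPosition(set, "chr1", c(99, 100, 200, 201))
containsPosition <- function(set, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  if (length(set) == 0L) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(.normChrom(chrom),
                              IRanges::IRanges(pos, width = 1L))
  s <- .normSeqlevels(set)
  lev <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lev
  GenomeInfoDb::seqlevels(s) <- lev
  GenomicRanges::countOverlaps(q, s) > 0L
}
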