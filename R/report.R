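## User-facing outputs: per-sample ROH table (TSV + companion BED3),
## genome-wide ideogram plot, gene-panel annotation.

#' @importFrom ggplot2 .data
NULL

#' Write the per-sample ROH table
#'
#' Writes a TSV with columns `chrom`, `start`, `end`, `size_bp`,
#' `n_variants`, `perc_homozygosity` (two decimals). Commented header lines
#' record the sample and every parameter value used, so the file is
#' self-describing. A companion BED3 file (same path with extension
#' `.bed`) encodes the same intervals in 0-based half-open coordinates.
#'
#' @param x a [RohSet].
#' @param path output TSV path.
#' @param bedPath companion BED path; default swaps the extension for
#'   `.bed`. Use `NA` to skip the BED.
#' @return Invisibly, `path`.
#' @export
writeRohTable <- function(x, path,
                          bedPath = paste0(tools::file_path_sans_ext(path),
                                           ".bed")) {
  stopifnot(is(x, "RohSet"))
  df <- rohTable(x)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e)
                    .stopFatal("autozyg_io_error",
                               paste("cannot write:", path)))
  on.exit(close(con))
  writeLines(c(
    "# autozyg ROH table",
    paste0("# sample=", x@sampleId),
    paste0("# parameters: ", .paramString(x@params)),
    paste(c("chrom", "start", "end", "size_bp", "n_variants",
            "perc_homozygosity"), collapse = "\t")
  ), con)
  if (nrow(df)) {
    df$perc_homozygosity <- sprintf("%.2f", df$perc_homozygosity)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.na(bedPath)) writeBed(x@rohs, bedPath)
  invisible(path)
}

#' Read back a ROH table written by writeRohTable
#'
#' @param path TSV path.
#' @return A [RohSet] (default parameters; sample id recovered from the
#'   header).
#' @export
readRohTable <- function(path) {
  if (!file.exists(path))
    .stopFatal("autozyg_io_error", paste("ROH table not found:", path))
  lines <- readLines(path)
  sample <- sub("^# sample=", "", grep("^# sample=", lines, value = TRUE))
  if (length(sample) != 1L) sample <- "sample"
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1L], "\t")[[1L]]
  if (length(body) > 1L) {
    df <- utils::read.table(text = body[-1L], sep = "\t",
                            col.names = header, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    mcols(gr)$nVariants <- as.integer(df$n_variants)
    mcols(gr)$nHomozygous <- as.integer(round(
      df$perc_homozygosity / 100 * df$n_variants))
    mcols(gr)$percHomozygous <- as.numeric(df$perc_homozygosity)
  } else {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$nVariants <- integer(0)
    mcols(gr)$nHomozygous <- integer(0)
    mcols(gr)$percHomozygous <- numeric(0)
  }
  new("RohSet", rohs = .sortGR(gr), sampleId = sample,
      params = rohParams(), log = list())
}

#' Genome-wide ROH plot
#'
#' Draws each chromosome to scale as a horizontal bar with detected ROHs as
#' filled blue spans, one row per chromosome, and writes a vector-format
#' (PDF) file when `path` is given. Renders cleanly with zero ROHs.
#'
#' @param x a [RohSet] (or `GRanges`).
#' @param chromLengths named vector of chromosome lengths (bp), or a
#'   [GenomeAnnotation]; chromosomes are drawn in this order.
#' @param path output PDF path, or NULL to skip writing.
#' @param title plot title.
#' @return Invisibly, a list with the plotted coordinate tables
#'   (`chromosomes`, `rohs`) and the `ggplot` object — identical for
#'   identical input.
#' @export
plotRohs <- function(x, chromLengths, path = NULL,
                     title = "Runs of homozygosity") {
  if (is(chromLengths, "GenomeAnnotation"))
    chromLengths <- chromLengths@chromLengths
  if (is.null(names(chromLengths)) || length(chromLengths) == 0L)
    stop("chromLengths must be a non-empty named vector")
  gr <- rohRanges(x)
  chromDf <- data.frame(chrom = names(chromLengths),
                        length = as.numeric(chromLengths),
                        y = rev(seq_along(chromLengths)),
                        stringsAsFactors = FALSE)
  idx <- match(.normChrom(as.character(GenomicRanges::seqnames(gr))),
               .normChrom(chromDf$chrom))
  rohDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      y = chromDf$y[idx],
                      stringsAsFactors = FALSE)
  rohDf <- rohDf[!is.na(rohDf$y), , drop = FALSE]
  h <- 0.32
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = chromDf,
      ggplot2::aes(xmin = 0, xmax = .data$length / 1e6,
                   ymin = .data$y - h, ymax = .data$y + h),
      fill = "grey92", colour = "grey35", linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = chromDf$y,
                                labels = chromDf$chrom,
                                expand = ggplot2::expansion(add = 0.7)) +
    ggplot2::labs(x = "Position (Mb)", y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (nrow(rohDf))
    p <- p + ggplot2::geom_rect(
      data = rohDf,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = .data$y - h, ymax = .data$y + h),
      fill = "#2166ac", colour = NA)
  if (!is.null(path)) {
    ok <- tryCatch({
      grDevices::pdf(path, width = 8, height = 6)
      print(p)
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .stopFatal("autozyg_io_error", paste("cannot write:", path))
  }
  invisible(list(chromosomes = chromDf, rohs = rohDf, plot = p))
}

#' Read a gene panel
#'
#' A gene panel is a tab-separated text file with columns gene symbol,
#' chromosome, start, end (1-based inclusive), optionally with a header
#' line. Symbols must be unique.
#'
#' @param path panel file path.
#' @return A `data.frame` with columns `gene`, `chrom`, `start`, `end`.
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path))
    .stopFatal("autozyg_io_error", paste("gene panel not found:", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    .stopFatal("autozyg_io_error",
               "gene panel needs 4 columns: gene, chrom, start, end")
  ## tolerate a header row
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L])))) df <- df[-1L, ]
  out <- data.frame(gene = as.character(df[[1L]]),
                    chrom = as.character(df[[2L]]),
                    start = as.numeric(df[[3L]]),
                    end = as.numeric(df[[4L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene))
    .stopFatal("autozyg_io_error", "gene panel symbols must be unique")
  if (any(is.na(out$start)) || any(is.na(out$end)) ||
      any(out$end < out$start) || any(out$start < 1))
    .stopFatal("autozyg_io_error", "gene panel has invalid coordinates")
  out
}

#' Annotate a gene panel against detected ROHs
#'
#' A gene counts as "in ROH" when its interval intersects any reported ROH
#' by at least one base pair (overlap, not containment — the clinically
#' conservative choice). Every panel gene is listed, with its overlapping
#' ROH or none.
#'
#' @param x a [RohSet] (or `GRanges`).
#' @param panel a gene panel `data.frame` (see [readGenePanel()]) or path.
#' @return A `data.frame`: `gene`, `chrom`, `start`, `end`, `in_roh`, and
#'   the overlapping ROH's coordinates (`roh_chrom`, `roh_start`,
#'   `roh_end`; NA when none).
#' @export
annotatePanel <- function(x, panel) {
  if (is.character(panel)) panel <- readGenePanel(panel)
  gr <- rohRanges(x)
  genes <- GenomicRanges::GRanges(.normChrom(panel$chrom),
                                  IRanges::IRanges(panel$start, panel$end))
  u <- .onCommonSeqlevels(genes, gr)
  hits <- GenomicRanges::findOverlaps(u$a, u$b, select = "first")
  out <- data.frame(panel,
                    in_roh = !is.na(hits),
                    roh_chrom = NA_character_,
                    roh_start = NA_real_,
                    roh_end = NA_real_,
                    stringsAsFactors = FALSE)
  hit <- !is.na(hits)
  if (any(hit)) {
    rg <- gr[hits[hit]]
    out$roh_chrom[hit] <- as.character(GenomicRanges::seqnames(rg))
    out$roh_start[hit] <- GenomicRanges::start(rg)
    out$roh_end[hit] <- GenomicRanges::end(rg)
  }
  out
}
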