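#' Build a VariantCalls object from vectors
#'
#' Low-level constructor used by the simulator and by tests; [readVcfCalls()]
#' is the usual entry point for real data. Calls are sorted by (chromosome,
#' position) on construction.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param zygosity character vector: "HOM_ALT", "HET" or "HEMI".
#' @param depth integer vector of total read counts.
#' @param altReads integer vector of alternative-allele read counts (NA when
#'   unknown; the allele fraction is then undefined).
#' @param ref,alt allele strings (defaults "A"/"G"; kept for round-tripping).
#' @param sampleId sample name.
#' @param stats list of parsing counters (internal use).
#' @return A [VariantCalls] object.
#' @export
#' @examples
#' variantCalls("chr1", c(100, 250), c("HOM_ALT", "HET"),
#'              depth = c(17L, 20L), altReads = c(17L, 11L))
variantCalls <- function(chrom, pos, zygosity, depth, altReads,
                         ref = "A", alt = "G",
                         sampleId = "sample", stats = list()) {
  n <- length(pos)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(as.character(chrom), n),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
  depth <- as.integer(rep_len(depth, n))
  altReads <- as.integer(rep_len(altReads, n))
  mcols(gr)$ref <- rep_len(as.character(ref), n)
  mcols(gr)$alt <- rep_len(as.character(alt), n)
  mcols(gr)$zygosity <- factor(rep_len(as.character(zygosity), n),
                               levels = c("HOM_ALT", "HET", "HEMI"))
  mcols(gr)$depth <- depth
  mcols(gr)$altReads <- altReads
  mcols(gr)$altFraction <- ifelse(depth > 0L & !is.na(altReads),
                                  altReads / depth, NA_real_)
  gr <- .sortGR(gr)
  new("VariantCalls", calls = gr, sampleId = sampleId, stats = stats)
}

#' Alternative-allele read fraction from AD or DP4 counts
#'
#' For AD-style counts `(ref, alt)` the fraction is `alt / (ref + alt)`; for
#' DP4-style counts `(ref_fwd, ref_rev, alt_fwd, alt_rev)` it is
#' `(alt_fwd + alt_rev) / sum`. When all counts are zero the fraction is
#' undefined (`NA`); such calls are later removed by the depth filter.
#'
#' @param counts integer vector of length 2 (AD) or 4 (DP4).
#' @return Fraction in `[0, 1]`, or `NA` if all counts are zero.
#' @export
#' @examples
#' computeAltFraction(c(9, 11))       # 0.55
#' computeAltFraction(c(5, 5, 5, 5))  # 0.5
computeAltFraction <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts) %in% c(2L, 4L))
    stop("counts must have length 2 (AD) or 4 (DP4)")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  alt <- if (length(counts) == 2L) counts[2L] else counts[3L] + counts[4L]
  alt / tot
}

## Extract one sample's column of a FORMAT field as a plain list, whatever
## layout readVcf chose (matrix of vectors, 3-d array, or plain matrix).
.genoColumn <- function(g, j) {
  if (is.null(g)) return(NULL)
  if (length(dim(g)) == 3L) {
    lapply(seq_len(dim(g)[1L]), function(i) g[i, j, ])
  } else {
    col <- g[, j]
    if (is.list(col)) col else as.list(col)
  }
}

#' Read variant calls for one sample from a VCF file
#'
#' Parses a VCF (v4.x, plain or bgzipped) into a [VariantCalls] object.
#' The file must carry the GT genotype field plus per-read-count information:
#' AD (allelic depths), DP4 (strand-split ref/alt counts, FORMAT or INFO), or
#' at least DP. Depth is taken from the first available source in the order
#' given by `depthSource` (default AD sum, then DP4 sum, then DP).
#'
#' Genotypes are mapped to zygosity as: two identical non-reference alleles
#' (`1/1`, `2|2`, ...) = `HOM_ALT`; two different alleles (`0/1`, `1/2`) =
#' `HET`; a single non-reference allele (`1`, haploid X/Y) = `HEMI`.
#' Records that are homozygous reference, have any missing allele, or carry
#' non-ACGT (symbolic / structural) alternative alleles are dropped and
#' counted; drops other than homozygous-reference are reported as one
#' warning and all counters are kept in the `stats` slot. Multiallelic
#' records are decomposed per alternative allele named by the genotype.
#'
#' @param path VCF file path.
#' @param sample sample name; required for multi-sample files.
#' @param depthSource character vector giving the precedence of depth
#'   sources, a permutation/subset of `c("AD", "DP4", "DP")`.
#' @return A [VariantCalls] object sorted by (chromosome, position).
#' @export
readVcfCalls <- function(path, sample = NULL,
                         depthSource = c("AD", "DP4", "DP")) {
  if (!file.exists(path))
    .stopFatal("autozyg_io_error", paste("VCF not found:", path))
  depthSource <- match.arg(depthSource, c("AD", "DP4", "DP"),
                           several.ok = TRUE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    .stopFatal("autozyg_unusable_vcf", "unusable VCF: no GT FORMAT field")
  samps <- colnames(gt)
  if (is.null(sample)) {
    if (length(samps) != 1L)
      .stopFatal("autozyg_unusable_vcf",
                 paste0("multi-sample VCF: choose one of ",
                        paste(samps, collapse = ", ")))
    sample <- samps[1L]
  }
  j <- match(sample, samps)
  if (is.na(j))
    .stopFatal("autozyg_unusable_vcf",
               paste0("sample '", sample, "' not present in VCF header"))

  adCol <- .genoColumn(VariantAnnotation::geno(vcf)$AD, j)
  dp4Col <- .genoColumn(VariantAnnotation::geno(vcf)$DP4, j)
  if (is.null(dp4Col) && "DP4" %in% colnames(VariantAnnotation::info(vcf)))
    dp4Col <- as.list(VariantAnnotation::info(vcf)$DP4)
  dpm <- VariantAnnotation::geno(vcf)$DP
  dpCol <- if (!is.null(dpm)) as.integer(dpm[, j]) else NULL
  if (is.null(adCol) && is.null(dp4Col))
    .stopFatal("autozyg_unusable_vcf",
               "unusable VCF: neither AD nor DP4 present in FORMAT/INFO")

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altC <- as.list(as(VariantAnnotation::alt(vcf), "CharacterList"))

  n <- nrow(gt)
  parts <- strsplit(gt[, j], "[/|]")
  lens <- lengths(parts)
  a1 <- rep(NA_character_, n); a2 <- rep(NA_character_, n)
  a1[lens >= 1L] <- vapply(parts[lens >= 1L], `[`, "", 1L)
  a2[lens >= 2L] <- vapply(parts[lens >= 2L], `[`, "", 2L)

  isMissing <- lens == 0L | is.na(a1) | a1 %in% c(".", "") |
    (lens >= 2L & (is.na(a2) | a2 %in% c(".", "")))
  badLen <- !isMissing & lens > 2L
  i1 <- suppressWarnings(as.integer(a1))
  i2 <- suppressWarnings(as.integer(a2))
  badParse <- !isMissing & !badLen &
    (is.na(i1) | (lens == 2L & is.na(i2)))
  ok <- !isMissing & !badLen & !badParse
  isHomRef <- ok & ((lens == 1L & i1 == 0L) |
                    (lens == 2L & i1 == 0L & i2 == 0L))
  isHemi <- ok & lens == 1L & i1 > 0L
  isHom <- ok & lens == 2L & i1 == i2 & i1 > 0L
  isHet <- ok & lens == 2L & i1 != i2
  hetHigh <- pmax(i1, i2)
  hetLow <- pmin(i1, i2)

  wHemi <- which(isHemi); wHom <- which(isHom); wHet <- which(isHet)
  wHet2 <- which(isHet & hetLow > 0L)          # e.g. GT 1/2: two alt rows
  recIdx <- c(wHemi, wHom, wHet, wHet2)
  altIdx <- c(i1[wHemi], i1[wHom], hetHigh[wHet], hetLow[wHet2])
  zyg <- c(rep("HEMI", length(wHemi)), rep("HOM_ALT", length(wHom)),
           rep("HET", length(wHet)), rep("HET", length(wHet2)))

  ## resolve alternative alleles; skip out-of-range and symbolic ALTs
  nAlts <- lengths(altC)
  inRange <- altIdx <= nAlts[recIdx]
  altAllele <- rep(NA_character_, length(recIdx))
  if (any(inRange))
    altAllele[inRange] <- mapply(function(i, k) altC[[i]][k],
                                 recIdx[inRange], altIdx[inRange])
  isSeq <- !is.na(altAllele) & grepl("^[ACGTacgt]+$", altAllele)
  dropSymbolic <- sum(inRange & !isSeq)
  dropMalformed <- sum(badLen) + sum(badParse) + sum(!inRange)
  keep <- inRange & isSeq
  recIdx <- recIdx[keep]; altIdx <- altIdx[keep]
  zyg <- zyg[keep]; altAllele <- altAllele[keep]
  m <- length(recIdx)

  ## depth / alt-read extraction with configurable source precedence
  adSum <- adAltMat <- NULL
  if (!is.null(adCol)) {
    adSum <- vapply(adCol, function(v) {
      v <- suppressWarnings(as.integer(v))
      if (length(v) < 2L || all(is.na(v))) NA_integer_
      else sum(v, na.rm = TRUE)
    }, integer(1))
  }
  dp4Sum <- dp4Alt <- NULL
  if (!is.null(dp4Col)) {
    d4 <- vapply(dp4Col, function(v) {
      v <- suppressWarnings(as.integer(v))
      if (length(v) != 4L || any(is.na(v))) c(NA_integer_, NA_integer_)
      else c(sum(v), v[3L] + v[4L])
    }, integer(2))
    dp4Sum <- d4[1L, ]; dp4Alt <- d4[2L, ]
  }

  depth <- rep(NA_integer_, m)
  altReads <- rep(NA_integer_, m)
  for (src in depthSource) {
    need <- is.na(depth)
    if (!any(need)) break
    if (src == "AD" && !is.null(adSum)) {
      v <- adSum[recIdx]
      a <- rep(NA_integer_, m)
      cand <- which(need & !is.na(v))
      if (length(cand))
        a[cand] <- mapply(function(i, k) {
          ad <- suppressWarnings(as.integer(adCol[[i]]))
          if (k + 1L <= length(ad) && !is.na(ad[k + 1L])) ad[k + 1L]
          else NA_integer_
        }, recIdx[cand], altIdx[cand])
      depth[cand] <- v[cand]
      altReads[cand] <- a[cand]
    } else if (src == "DP4" && !is.null(dp4Sum)) {
      v <- dp4Sum[recIdx]
      set <- need & !is.na(v)
      depth[set] <- v[set]
      altReads[set] <- dp4Alt[recIdx][set]
    } else if (src == "DP" && !is.null(dpCol)) {
      v <- dpCol[recIdx]
      set <- need & !is.na(v)
      depth[set] <- v[set]
    }
  }
  depth[is.na(depth)] <- 0L

  gr <- GenomicRanges::GRanges(chrom[recIdx],
                               IRanges::IRanges(pos[recIdx], width = 1L))
  mcols(gr)$ref <- refA[recIdx]
  mcols(gr)$alt <- altAllele
  mcols(gr)$zygosity <- factor(zyg, levels = c("HOM_ALT", "HET", "HEMI"))
  mcols(gr)$depth <- depth
  mcols(gr)$altReads <- altReads
  mcols(gr)$altFraction <- ifelse(depth > 0L & !is.na(altReads),
                                  altReads / depth, NA_real_)

  ## drop exact duplicates on (chrom, pos, alt)
  key <- paste(chrom[recIdx], pos[recIdx], altAllele, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) gr <- gr[!dup]
  gr <- .sortGR(gr)

  stats <- list(droppedMissing = sum(isMissing),
                droppedHomRef = sum(isHomRef),
                droppedSymbolic = dropSymbolic,
                droppedMalformed = dropMalformed,
                duplicatesRemoved = sum(dup))
  nDropped <- stats$droppedMissing + dropSymbolic + dropMalformed
  if (nDropped > 0L)
    warning(sprintf(
      "dropped %d record(s): %d missing genotype, %d symbolic ALT, %d malformed",
      nDropped, stats$droppedMissing, dropSymbolic, dropMalformed))

  new("VariantCalls", calls = gr, sampleId = sample, stats = stats)
}

#' Write a VariantCalls object as a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 with GT, AD and DP FORMAT fields,
#' suitable for re-reading with [readVcfCalls()] (round-trip preserves
#' chromosome, position, zygosity and depth). Used by the synthetic-data
#' generator.
#'
#' @param x a [VariantCalls] object.
#' @param path output file path.
#' @param chromLengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
writeVcfCalls <- function(x, path, chromLengths = NULL) {
  gr <- x@calls
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(chromLengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chromLengths), as.integer(chromLengths)))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", GenomeInfoDb::seqlevels(gr)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x@sampleId, sep = "\t"))
  writeLines(hdr, con)
  if (length(gr)) {
    z <- as.character(mcols(gr)$zygosity)
    gtf <- c(HOM_ALT = "1/1", HET = "0/1", HEMI = "1")[z]
    depth <- mcols(gr)$depth
    altReads <- mcols(gr)$altReads
    altReads[is.na(altReads)] <- 0L
    refReads <- pmax(depth - altReads, 0L)
    rows <- paste(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), ".",
                  mcols(gr)$ref, mcols(gr)$alt, ".", "PASS", ".",
                  "GT:AD:DP",
                  paste0(gtf, ":", refReads, ",", altReads, ":", depth),
                  sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
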