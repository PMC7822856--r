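## Independent brute-force oracles and small fixture builders.
## Oracles are deliberately naive re-derivations, kept free of any package
## internals they are used to check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Exact two-sided binomial p at p0 = 0.5 by literal pmf summation:
## sum of choose(n, i) / 2^n over all outcomes no more probable than k.
bruteBinomTwoSided <- function(k, n) {
  pmf <- choose(n, 0:n) * 0.5^n
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

## Sliding-window coverage by explicit enumeration of every window.
## Returns a logical coverage vector over the variant indices.
bruteWindowCover <- function(hom, window, thres) {
  n <- length(hom)
  covered <- logical(n)
  if (n >= window) {
    for (j in seq_len(n - window + 1)) {
      if (sum(hom[j:(j + window - 1)]) >= thres) {
        covered[j:(j + window - 1)] <- TRUE
      }
    }
  }
  covered
}

## Maximal runs of TRUE as a two-column matrix of (from, to) indices.
coverRuns <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(from = starts[r$values], to = ends[r$values])
}

## Base-pair overlap of two interval lists by per-base membership counting.
## Intervals are 1-based inclusive data.frames (chrom, start, end).
bruteOverlapBp <- function(a, b) {
  total <- 0
  for (ch in union(a$chrom, b$chrom)) {
    aa <- a[a$chrom == ch, , drop = FALSE]
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(aa) == 0 || nrow(bb) == 0) next
    maxPos <- max(aa$end, bb$end)
    inA <- logical(maxPos)
    inB <- logical(maxPos)
    for (i in seq_len(nrow(aa))) inA[aa$start[i]:aa$end[i]] <- TRUE
    for (i in seq_len(nrow(bb))) inB[bb$start[i]:bb$end[i]] <- TRUE
    total <- total + sum(inA & inB)
  }
  total
}

grFromDf <- function(df) {
  GRanges(df$chrom, IRanges(df$start, df$end))
}

## Write a VCF fixture from body rows, with a standard header.
writeVcfFixture <- function(rows, samples = "S1",
                            formats = c("GT", "AD", "DP"),
                            infoDp4 = FALSE, contigs = c("chr1", "chr2")) {
  path <- tempfile(fileext = ".vcf")
  fmtDefs <- c(
    GT = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    AD = '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    DP = '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">'
  )
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", contigs),
           unname(fmtDefs[formats]))
  if (infoDp4) {
    hdr <- c(hdr,
      '##INFO=<ID=DP4,Number=4,Type=Integer,Description="Strand counts">')
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

## Small simulated dataset shared by detection tests: 3 chromosomes of
## 60 Mb with two planted segments, reduced scale for speed.
smallSim <- function(seed = 42, noise = 0, ...) {
  simulateRohData(simConfig(
    seed = seed, nChromosomes = 3, chromLength = 6e7,
    plantedSegments = data.frame(chrom = c("chr1", "chr2"),
                                 start = c(1e7, 3.5e7),
                                 end = c(2e7 - 1, 4.5e7 - 1)),
    inRohFalseHetRate = noise, ...))
}

smallParams <- function(...) {
  rohParams(minSurvivingVariants = 0, ...)
}
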