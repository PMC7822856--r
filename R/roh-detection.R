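## ROH detection: sliding-window seeding, trimming, extension, gap
## splitting, final filtering, and the full composed pipeline.

## Homozygosity indicator: hemizygous calls count as homozygous (male X
## rule; vacuous elsewhere), heterozygous calls do not.
.homMask <- function(gr) {
  as.character(mcols(gr)$zygosity) %in% c("HOM_ALT", "HEMI")
}

## Index runs of covered variants for one chromosome.
## hom: logical vector in position order. Returns matrix [ , c(from, to)].
.seedRuns <- function(hom, window, thres) {
  n <- length(hom)
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (n < window) return(empty)
  cs <- cumsum(c(0L, as.integer(hom)))
  wsum <- cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]
  pass <- which(wsum >= thres)
  if (length(pass) == 0L) return(empty)
  ## a variant is covered iff it lies in >= 1 passing window: mark the
  ## union of [j, j + window - 1] with a difference array
  add <- tabulate(pass, nbins = n + 1L)
  sub <- tabulate(pass + window, nbins = n + 1L)
  covered <- cumsum(add - sub)[seq_len(n)] > 0L
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(from = starts[r$values], to = ends[r$values])
}

#' Seed candidate ROHs with a sliding window
#'
#' Slides a window of `window` consecutive variants (one variant at a time)
#' along each chromosome; a window passes when it holds at least
#' `windowThres` homozygous variants. Candidate ROHs are maximal runs of
#' variants covered by at least one passing window, spanning from the first
#' to the last covered variant's position. Chromosomes with fewer variants
#' than the window size yield no candidates.
#'
#' @param x a filtered [VariantCalls] object.
#' @param params a [RohParams].
#' @return A `GRanges` of candidate ROHs (no statistics attached yet).
#' @export
seedWindows <- function(x, params = rohParams()) {
  gr <- x@calls
  out <- GenomicRanges::GRanges()
  if (length(gr) == 0L) return(out)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  hom <- .homMask(gr)
  pos <- GenomicRanges::start(gr)
  pieces <- lapply(unique(chroms), function(ch) {
    sel <- chroms == ch
    runs <- .seedRuns(hom[sel], params@window, params@windowThres)
    if (nrow(runs) == 0L) return(NULL)
    p <- pos[sel]
    data.frame(chrom = ch, start = p[runs[, "from"]], end = p[runs[, "to"]])
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || nrow(df) == 0L) return(out)
  .sortGR(GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end)))
}

## Member-call indices of each ROH (any zygosity, surviving calls only).
.members <- function(rohs, gr) {
  hits <- GenomicRanges::findOverlaps(rohs, gr)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_along(rohs)))
}

#' Trim candidate ROHs to homozygous boundaries
#'
#' Moves each candidate's start and end inward to the outermost homozygous
#' variants it contains; candidates with no homozygous variant are
#' discarded.
#'
#' @param candidates a `GRanges` of candidates (from [seedWindows()]).
#' @param x the [VariantCalls] the candidates were seeded from.
#' @return A `GRanges` of trimmed candidates.
#' @export
trimCandidates <- function(candidates, x) {
  if (length(candidates) == 0L) return(candidates)
  gr <- x@calls
  hom <- .homMask(gr)
  pos <- GenomicRanges::start(gr)
  mem <- .members(candidates, gr)
  newStart <- rep(NA_real_, length(candidates))
  newEnd <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    hm <- mem[[i]][hom[mem[[i]]]]
    if (length(hm) == 0L) next
    newStart[i] <- min(pos[hm])
    newEnd[i] <- max(pos[hm])
  }
  keep <- !is.na(newStart)
  out <- candidates[keep]
  IRanges::ranges(out) <- IRanges::IRanges(start = newStart[keep],
                                           end = newEnd[keep])
  out
}

#' Extend ROH boundaries outward
#'
#' Each boundary moves outward by up to `extendMb` megabases, stopping early
#' at the chromosome end or just inside the nearest surviving heterozygous
#' variant outside the ROH (extension never re-absorbs a heterozygous call
#' that trimming excluded). ROHs that overlap or abut after extension are
#' merged.
#'
#' @param rohs trimmed, sorted `GRanges` of ROHs.
#' @param x the filtered [VariantCalls].
#' @param annotation a [GenomeAnnotation] providing chromosome lengths;
#'   chromosomes without a known length are capped at the last variant
#'   position plus the extension.
#' @param params a [RohParams].
#' @return A merged `GRanges`.
#' @export
extendRohs <- function(rohs, x, annotation = genomeAnnotation(),
                       params = rohParams()) {
  if (length(rohs) == 0L) return(rohs)
  gr <- x@calls
  hom <- .homMask(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  extBp <- params@extendMb * .MB
  lens <- annotation@chromLengths
  lnames <- .normChrom(names(lens))

  rchrom <- as.character(GenomicRanges::seqnames(rohs))
  newStart <- numeric(length(rohs))
  newEnd <- numeric(length(rohs))
  for (i in seq_along(rohs)) {
    ch <- rchrom[i]
    s <- GenomicRanges::start(rohs)[i]
    e <- GenomicRanges::end(rohs)[i]
    hetPos <- pos[chroms == ch & !hom]
    leftHet <- hetPos[hetPos < s]
    rightHet <- hetPos[hetPos > e]
    lo <- max(1, s - extBp,
              if (length(leftHet)) max(leftHet) + 1 else -Inf)
    chLen <- lens[match(.normChrom(ch), lnames)]
    if (is.na(chLen)) chLen <- max(pos[chroms == ch]) + extBp
    hi <- min(chLen, e + extBp,
              if (length(rightHet)) min(rightHet) - 1 else Inf)
    newStart[i] <- lo
    newEnd[i] <- hi
  }
  ext <- GenomicRanges::GRanges(rchrom,
                                IRanges::IRanges(start = newStart,
                                                 end = newEnd))
  .sortGR(GenomicRanges::reduce(ext))  # merges overlapping and abutting
}

#' Split ROHs at large variant-free stretches
#'
#' Whenever two consecutive member variants of an ROH lie more than
#' `maxGapMb` megabases apart, the ROH is split at those variants'
#' positions; the empty stretch belongs to neither part. Applies to every
#' such stretch (recursively). ROHs left without member variants are
#' dropped.
#'
#' @param rohs a `GRanges` of ROHs.
#' @param x the filtered [VariantCalls].
#' @param params a [RohParams].
#' @return A `GRanges`, possibly with more (smaller) ROHs.
#' @export
splitOnGaps <- function(rohs, x, params = rohParams()) {
  if (length(rohs) == 0L) return(rohs)
  gr <- x@calls
  pos <- GenomicRanges::start(gr)
  mem <- .members(rohs, gr)
  gapBp <- params@maxGapMb * .MB
  chrom <- character(0); starts <- numeric(0); ends <- numeric(0)
  for (i in seq_along(rohs)) {
    p <- sort(pos[mem[[i]]])
    if (length(p) == 0L) next
    ch <- as.character(GenomicRanges::seqnames(rohs))[i]
    s <- GenomicRanges::start(rohs)[i]
    e <- GenomicRanges::end(rohs)[i]
    gaps <- which(diff(p) > gapBp)
    if (length(gaps) == 0L) {
      chrom <- c(chrom, ch); starts <- c(starts, s); ends <- c(ends, e)
    } else {
      ss <- c(s, p[gaps + 1L])
      ee <- c(p[gaps], e)
      chrom <- c(chrom, rep(ch, length(ss)))
      starts <- c(starts, ss); ends <- c(ends, ee)
    }
  }
  .sortGR(GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends)))
}

## Attach nVariants / nHomozygous / percHomozygous over the surviving calls
## within each ROH.
.annotateRohStats <- function(rohs, x) {
  gr <- x@calls
  if (length(rohs) == 0L) {
    mcols(rohs)$nVariants <- integer(0)
    mcols(rohs)$nHomozygous <- integer(0)
    mcols(rohs)$percHomozygous <- numeric(0)
    return(rohs)
  }
  hom <- .homMask(gr)
  mem <- .members(rohs, gr)
  nv <- vapply(mem, length, integer(1))
  nh <- vapply(mem, function(ix) sum(hom[ix]), integer(1))
  mcols(rohs)$nVariants <- unname(nv)
  mcols(rohs)$nHomozygous <- unname(nh)
  mcols(rohs)$percHomozygous <- unname(ifelse(nv > 0L, 100 * nh / nv, 0))
  rohs
}

#' Final ROH filter
#'
#' Keeps an ROH iff its size is at least `minSizeMb` megabases, it holds at
#' least `minVar` variants, and its percent homozygosity is at least
#' `minPerc` (all inclusive bounds).
#'
#' @param rohs a `GRanges` with `nVariants` / `percHomozygous` columns (as
#'   produced inside [detectRohs()]), or the output of [splitOnGaps()]
#'   combined with `x` to recompute statistics.
#' @param params a [RohParams].
#' @param x optionally, the [VariantCalls] to (re)compute statistics from.
#' @return The filtered `GRanges`.
#' @export
finalFilter <- function(rohs, params = rohParams(), x = NULL) {
  if (!is.null(x)) rohs <- .annotateRohStats(rohs, x)
  if (length(rohs) == 0L) return(rohs)
  keep <- GenomicRanges::width(rohs) >= params@minSizeMb * .MB &
    mcols(rohs)$nVariants >= params@minVar &
    mcols(rohs)$percHomozygous >= params@minPerc - 1e-9
  rohs[keep]
}

## Infer sample sex from the X heterozygosity rate among surviving X calls.
.inferSex <- function(gr) {
  isX <- .normChrom(as.character(GenomicRanges::seqnames(gr))) == "X"
  if (!any(isX)) return("female")
  z <- as.character(mcols(gr)$zygosity[isX])
  hetRate <- mean(z == "HET")
  if (hetRate < 0.05) "male" else "female"
}

#' Detect runs of homozygosity
#'
#' The full pipeline: repeat-region removal, variant-level quality filter
#' (depth, allele balance, exact binomial test), minimum-variant check,
#' then per chromosome sliding-window seeding, trimming to homozygous
#' boundaries, boundary extension, splitting at large variant-free
#' stretches, and the final size / variant-count / percent-homozygosity
#' filter.
#'
#' Chromosome Y and the mitochondrial contig are never analysed; chromosome
#' X only when `params@includeChrX`. Hemizygous calls (male X) count as
#' homozygous; a diploid (female) X is treated like an autosome.
#'
#' @param x a [VariantCalls] object (raw, as read by [readVcfCalls()]).
#' @param annotation a [GenomeAnnotation] (repeats used for filtering,
#'   chromosome lengths for extension).
#' @param params a [RohParams].
#' @param oneSidedBinomial use a one-sided binomial filter (see
#'   [qualityFilter()]).
#' @return A [RohSet]: sorted, disjoint ROHs with per-ROH statistics, the
#'   parameters used, and per-stage accounting in `filterLog()`.
#' @export
detectRohs <- function(x, annotation = genomeAnnotation(),
                       params = rohParams(), oneSidedBinomial = FALSE) {
  stopifnot(is(x, "VariantCalls"), is(annotation, "GenomeAnnotation"),
            is(params, "RohParams"))
  gr <- x@calls
  norm <- .normChrom(as.character(GenomicRanges::seqnames(gr)))
  dropChrom <- norm %in% c("Y", "M", "MT") |
    (!params@includeChrX & norm == "X")
  x@calls <- gr[!dropChrom]
  nOffTarget <- sum(dropChrom)

  sex <- params@sex
  if (sex == "auto")
    sex <- if (params@includeChrX) .inferSex(x@calls) else "female"

  x <- removeRepeatVariants(x, annotation@repeats)
  qf <- qualityFilter(x, params, oneSided = oneSidedBinomial)
  assertMinVariants(qf$calls, params)

  cand <- seedWindows(qf$calls, params)
  trimmed <- trimCandidates(cand, qf$calls)
  extended <- extendRohs(trimmed, qf$calls, annotation, params)
  splitted <- splitOnGaps(extended, qf$calls, params)
  final <- finalFilter(.annotateRohStats(splitted, qf$calls), params)

  new("RohSet",
      rohs = final,
      sampleId = x@sampleId,
      params = params,
      log = list(report = qf$report,
                 sexUsed = sex,
                 offTargetChromCalls = nOffTarget,
                 candidates = length(cand),
                 trimmed = length(trimmed),
                 extended = length(extended),
                 afterGapSplit = length(splitted),
                 final = length(final)))
}

#' Tabulate a RohSet
#'
#' @param x a [RohSet] (or a `GRanges` with ROH statistic columns).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `size_bp`,
#'   `n_variants`, `perc_homozygosity`.
#' @export
rohTable <- function(x) {
  gr <- rohRanges(x)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    size_bp = GenomicRanges::width(gr),
    n_variants = as.integer(mcols(gr)$nVariants),
    perc_homozygosity = round(as.numeric(mcols(gr)$percHomozygous), 2),
    stringsAsFactors = FALSE
  )
}
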