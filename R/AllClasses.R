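#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

#' Algorithm parameters for ROH detection
#'
#' Holds the eleven tunable parameters of the homozygosity-mapping algorithm:
#' the variant-level quality thresholds (depth, allele-balance window, exact
#' binomial p-value, minimum surviving variants) and the segment-level
#' detection thresholds (sliding-window geometry, maximum internal gap,
#' boundary extension, and the final size / variant-count / percent-homozygous
#' filters). Construct with [rohParams()].
#'
#' @slot minDepth integer, minimum read depth per call (reads).
#' @slot minAltFraction,maxAltFraction numeric, inclusive allele-balance
#'   bounds applied to heterozygous calls.
#' @slot binomialP numeric, exact two-sided binomial p-value threshold below
#'   which a heterozygous call is removed.
#' @slot minSurvivingVariants integer, the analysis stops when fewer variants
#'   survive filtering.
#' @slot window,windowThres integer, sliding-window size in variants and the
#'   minimum number of homozygous variants for a window to pass.
#' @slot maxGapMb numeric, maximum variant-free stretch (Mb) tolerated inside
#'   an ROH before it is split.
#' @slot extendMb numeric, maximum boundary extension (Mb).
#' @slot minSizeMb,minVar,minPerc numeric/integer/numeric, final ROH filters:
#'   minimum size (Mb), minimum variant count, minimum percent homozygous.
#' @slot includeChrX logical, whether chromosome X is analysed.
#' @slot sex character, "male", "female" or "auto" (X heterozygosity
#'   heuristic); affects only run metadata, see the package vignette.
#' @aliases RohParams
#' @exportClass RohParams
setClass("RohParams", representation(
  minDepth = "integer",
  minAltFraction = "numeric",
  maxAltFraction = "numeric",
  binomialP = "numeric",
  minSurvivingVariants = "integer",
  window = "integer",
  windowThres = "integer",
  maxGapMb = "numeric",
  extendMb = "numeric",
  minSizeMb = "numeric",
  minVar = "integer",
  minPerc = "numeric",
  includeChrX = "logical",
  sex = "character"
))

setValidity("RohParams", function(object) {
  msg <- character(0)
  ok1 <- function(x) length(x) == 1L && !is.na(x)
  if (!ok1(object@minDepth) || object@minDepth < 0L)
    msg <- c(msg, "minDepth must be a single integer >= 0")
  if (!ok1(object@minAltFraction) || !ok1(object@maxAltFraction) ||
      object@minAltFraction < 0 || object@maxAltFraction > 1 ||
      object@minAltFraction >= object@maxAltFraction)
    msg <- c(msg, "need 0 <= minAltFraction < maxAltFraction <= 1")
  if (!ok1(object@binomialP) || object@binomialP <= 0 || object@binomialP >= 1)
    msg <- c(msg, "binomialP must be in (0, 1)")
  if (!ok1(object@minSurvivingVariants) || object@minSurvivingVariants < 0L)
    msg <- c(msg, "minSurvivingVariants must be >= 0")
  if (!ok1(object@window) || !ok1(object@windowThres) ||
      object@windowThres < 1L || object@windowThres > object@window)
    msg <- c(msg, "need 1 <= windowThres <= window")
  if (!ok1(object@maxGapMb) || object@maxGapMb <= 0)
    msg <- c(msg, "maxGapMb must be > 0")
  if (!ok1(object@extendMb) || object@extendMb < 0)
    msg <- c(msg, "extendMb must be >= 0")
  if (!ok1(object@minSizeMb) || object@minSizeMb <= 0)
    msg <- c(msg, "minSizeMb must be > 0")
  if (!ok1(object@minVar) || object@minVar < 0L)
    msg <- c(msg, "minVar must be >= 0")
  if (!ok1(object@minPerc) || object@minPerc < 0 || object@minPerc > 100)
    msg <- c(msg, "minPerc must be in [0, 100]")
  if (!ok1(object@includeChrX))
    msg <- c(msg, "includeChrX must be TRUE or FALSE")
  if (length(object@sex) != 1L || !object@sex %in% c("male", "female", "auto"))
    msg <- c(msg, "sex must be one of 'male', 'female', 'auto'")
  if (length(msg)) msg else TRUE
})

#' Per-sample variant calls
#'
#' The variant-call table for one sample: a sorted `GRanges` (one range per
#' call, width = 1 at the variant position) with metadata columns `ref`,
#' `alt`, `zygosity` (factor: `HOM_ALT`, `HET`, `HEMI`), `depth`, `altReads`
#' and `altFraction`. Parsing statistics (dropped-record counters) live in
#' the `stats` slot. Construct by [readVcfCalls()] or [variantCalls()].
#'
#' @slot calls GRanges of variant positions with call metadata columns.
#' @slot sampleId character scalar.
#' @slot stats list of parsing / filtering counters.
#' @aliases VariantCalls
#' @exportClass VariantCalls
setClass("VariantCalls", representation(
  calls = "GRanges",
  sampleId = "character",
  stats = "list"
))

setValidity("VariantCalls", function(object) {
  gr <- object@calls
  msg <- character(0)
  need <- c("zygosity", "depth", "altReads", "altFraction")
  if (!all(need %in% names(mcols(gr))))
    msg <- c(msg, paste("calls need mcols:", paste(need, collapse = ", ")))
  else {
    if (length(gr)) {
      if (any(GenomicRanges::start(gr) < 1L))
        msg <- c(msg, "positions must be >= 1")
      d <- mcols(gr)$depth
      if (any(is.na(d)) || any(d < 0L))
        msg <- c(msg, "depth must be a non-negative integer")
      af <- mcols(gr)$altFraction
      bad <- !is.na(af) & (af < 0 | af > 1)
      if (any(bad)) msg <- c(msg, "altFraction must be in [0,1] or NA")
      if (any(d > 0L & is.na(af) & !is.na(mcols(gr)$altReads)))
        msg <- c(msg, "altFraction must be defined when depth > 0 and altReads known")
      if (!all(levels(factor(mcols(gr)$zygosity)) %in%
               c("HOM_ALT", "HET", "HEMI")))
        msg <- c(msg, "zygosity must be HOM_ALT, HET or HEMI")
      if (length(gr) > 1L) {
        key <- as.integer(GenomicRanges::seqnames(gr)) * 2^32 +
          GenomicRanges::start(gr)
        if (is.unsorted(key))
          msg <- c(msg, "calls must be sorted by (chrom, pos)")
      }
    }
  }
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Genome annotation resources
#'
#' Interval resources the detector and the evaluation metrics depend on:
#' repeat regions (UCSC-style repeat track exported as BED), assembly gap
#' regions (centromeres, telomeres, short arms, heterochromatin) and
#' chromosome lengths. Construct with [genomeAnnotation()].
#'
#' @slot repeats GRanges of repeat regions (merged).
#' @slot gaps GRanges of assembly gap regions (merged).
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#' @aliases GenomeAnnotation
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation", representation(
  repeats = "GRanges",
  gaps = "GRanges",
  chromLengths = "numeric"
))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  len <- object@chromLengths
  if (length(len) && (is.null(names(len)) || any(!is.finite(len)) || any(len <= 0)))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  for (nm in c("repeats", "gaps")) {
    gr <- slot(object, nm)
    if (length(gr) && length(len)) {
      chr <- .normChrom(as.character(GenomicRanges::seqnames(gr)))
      idx <- match(chr, .normChrom(names(len)))
      known <- !is.na(idx)
      if (any(GenomicRanges::end(gr)[known] > len[idx[known]]))
        msg <- c(msg, sprintf("%s intervals exceed chromosome length", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Variant-filter accounting
#'
#' Counts of variant calls removed per criterion (repeat region, depth,
#' allele balance, binomial test, missing genotype) plus the surviving
#' count. Counts are conserved: removed + surviving = input.
#'
#' @slot input integer, calls entering the filter.
#' @slot surviving integer, calls surviving all criteria.
#' @slot removed named integer vector with elements `repeat`, `depth`,
#'   `alt_fraction`, `binomial`, `missing`.
#' @aliases FilterReport
#' @exportClass FilterReport
setClass("FilterReport", representation(
  input = "integer",
  surviving = "integer",
  removed = "integer"
))

setValidity("FilterReport", function(object) {
  need <- c("repeat", "depth", "alt_fraction", "binomial", "missing")
  if (!identical(sort(names(object@removed)), sort(need)))
    return("removed must be named: repeat, depth, alt_fraction, binomial, missing")
  if (sum(object@removed) + object@surviving != object@input)
    return("removed counts + surviving must equal input")
  TRUE
})

#' A set of detected runs of homozygosity
#'
#' Result container for one sample: a sorted, disjoint `GRanges` of ROHs
#' (1-based inclusive coordinates) with metadata columns `nVariants`,
#' `nHomozygous` and `percHomozygous`, plus the parameters used and
#' per-stage filter accounting.
#'
#' @slot rohs GRanges with ROH statistics in mcols.
#' @slot sampleId character scalar.
#' @slot params the [RohParams] used for detection.
#' @slot log list: stage counters, including the [FilterReport].
#' @aliases RohSet
#' @exportClass RohSet
setClass("RohSet", representation(
  rohs = "GRanges",
  sampleId = "character",
  params = "RohParams",
  log = "list"
))

setValidity("RohSet", function(object) {
  gr <- object@rohs
  msg <- character(0)
  need <- c("nVariants", "nHomozygous", "percHomozygous")
  if (!all(need %in% names(mcols(gr))))
    msg <- c(msg, paste("rohs need mcols:", paste(need, collapse = ", ")))
  else if (length(gr)) {
    if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
      msg <- c(msg, "end must be >= start")
    if (any(mcols(gr)$nHomozygous > mcols(gr)$nVariants))
      msg <- c(msg, "nHomozygous must be <= nVariants")
    p <- mcols(gr)$percHomozygous
    if (any(p < 0 | p > 100)) msg <- c(msg, "percHomozygous must be in [0,100]")
    if (!all(GenomicRanges::isDisjoint(gr)))
      msg <- c(msg, "ROHs must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' ROH evaluation result
#'
#' Base-pair overlap metrics of a test ROH set against a reference ROH set:
#' sensitivity, specificity and their harmonic mean (F-score), all in
#' percent, with the underlying base-pair totals. Construct with
#' [evaluateRohs()] or [truthCompare()].
#'
#' @slot sensitivity,specificity,fScore numeric percent (NA when undefined).
#' @slot refBp,testBp numeric, total bp of the filtered reference and
#'   filtered test sets entering the two ratios.
#' @slot sensOverlapBp,specOverlapBp numeric, overlap bp in the numerator of
#'   each ratio.
#' @aliases RohEvaluation
#' @exportClass RohEvaluation
setClass("RohEvaluation", representation(
  sensitivity = "numeric",
  specificity = "numeric",
  fScore = "numeric",
  refBp = "numeric",
  testBp = "numeric",
  sensOverlapBp = "numeric",
  specOverlapBp = "numeric"
))

setValidity("RohEvaluation", function(object) {
  msg <- character(0)
  for (nm in c("sensitivity", "specificity", "fScore")) {
    v <- slot(object, nm)
    if (length(v) != 1L) msg <- c(msg, paste(nm, "must be length 1"))
    else if (!is.na(v) && (v < 0 || v > 100))
      msg <- c(msg, paste(nm, "must be in [0,100]"))
  }
  if (length(msg)) msg else TRUE
})
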