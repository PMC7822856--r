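#' Exact two-sided binomial p-value for allele balance
#'
#' Exact two-sided test of `altReads` successes in `totalReads` trials
#' against success probability 0.5: the p-value is the sum of the
#' probabilities of all outcomes no more probable than the observed one
#' (minimum-likelihood definition, computed by summation of the binomial
#' probability mass function). True heterozygotes have allele balance near
#' 0.5 and p near 1; allele-skewed artifacts get vanishingly small p.
#'
#' @param altReads integer vector, alternative-read counts.
#' @param totalReads integer vector, total read counts (>= 1).
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' binomialTwoSidedP(10, 20)  # 1: dead-centre allele balance
#' binomialTwoSidedP(0, 3)    # 0.25: outcomes {0, 3} each have mass 1/8
binomialTwoSidedP <- function(altReads, totalReads) {
  k <- as.integer(altReads)
  n <- as.integer(totalReads)
  len <- max(length(k), length(n))
  k <- rep_len(k, len)
  n <- rep_len(n, len)
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1L) || any(k < 0L) ||
      any(k > n))
    stop("need 0 <= altReads <= totalReads and totalReads >= 1")
  vapply(seq_len(len), function(i) {
    d <- stats::dbinom(0:n[i], n[i], 0.5)
    ## relative tolerance guards against ties broken by floating-point dust
    min(1, sum(d[d <= d[k[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Remove variant calls inside repeat regions
#'
#' Drops every call whose position lies in the repeat interval set; the
#' first filtering stage of the detector.
#'
#' @param x a [VariantCalls] object (sorted).
#' @param repeats repeat regions as a `GRanges` (e.g. from [loadBed()]).
#' @return A [VariantCalls] with the `removedRepeat` counter updated in
#'   `x@stats`.
#' @export
removeRepeatVariants <- function(x, repeats) {
  gr <- x@calls
  if (length(repeats) == 0L || length(gr) == 0L) {
    x@stats$removedRepeat <- 0L
    return(x)
  }
  inRep <- containsPosition(repeats,
                            as.character(GenomicRanges::seqnames(gr)),
                            GenomicRanges::start(gr))
  x@calls <- gr[!inRep]
  x@stats$removedRepeat <- sum(inRep)
  x
}

#' Variant-level quality filter
#'
#' The call-level screen that removes unreliable variants before ROH
#' detection. A call survives iff its depth is at least `minDepth` and — for
#' heterozygous calls only — its allele fraction lies within
#' `[minAltFraction, maxAltFraction]` (inclusive) and the exact two-sided
#' binomial p-value of its read counts is at least `binomialP`. Homozygous
#' and hemizygous calls face only the depth criterion. Heterozygous calls
#' with undefined allele fraction (no per-allele counts) are removed.
#' Each call is removed individually; the surviving set is independent of
#' the order in which criteria are applied (only the per-reason counts in
#' the report depend on the fixed order depth, allele fraction, binomial).
#'
#' @param x a [VariantCalls] object.
#' @param params a [RohParams] object (see [rohParams()]).
#' @param oneSided apply a one-sided binomial test (upper tail of the
#'   alt-read count) instead of the default two-sided test.
#' @return A list with elements `calls` (filtered [VariantCalls]) and
#'   `report` (a [FilterReport]; the `repeat` and `missing` slots carry any
#'   counts already accumulated in `x@stats`).
#' @export
qualityFilter <- function(x, params = rohParams(), oneSided = FALSE) {
  gr <- x@calls
  nIn <- length(gr)
  depth <- mcols(gr)$depth
  zyg <- as.character(mcols(gr)$zygosity)
  af <- mcols(gr)$altFraction
  altReads <- mcols(gr)$altReads

  failDepth <- depth < params@minDepth
  isHet <- zyg == "HET"
  afBad <- isHet & (is.na(af) | af < params@minAltFraction |
                    af > params@maxAltFraction)
  failAf <- !failDepth & afBad

  ## binomial test only reached by het calls that passed depth + balance
  candidate <- isHet & !failDepth & !failAf
  failBinom <- rep(FALSE, nIn)
  idx <- which(candidate & !is.na(altReads) & depth >= 1L)
  if (length(idx)) {
    p <- if (oneSided) {
      stats::pbinom(altReads[idx] - 1L, depth[idx], 0.5, lower.tail = FALSE)
    } else {
      binomialTwoSidedP(altReads[idx], depth[idx])
    }
    failBinom[idx] <- p < params@binomialP
  }

  keep <- !(failDepth | failAf | failBinom)
  x@calls <- gr[keep]
  report <- new("FilterReport",
                input = nIn + sum(unlist(x@stats[c("removedRepeat",
                                                   "droppedMissing")]),
                                  na.rm = TRUE),
                surviving = sum(keep),
                removed = c(
                  "repeat" = as.integer(x@stats$removedRepeat %||% 0L),
                  depth = sum(failDepth),
                  alt_fraction = sum(failAf),
                  binomial = sum(failBinom),
                  missing = as.integer(x@stats$droppedMissing %||% 0L)))
  x@stats$removedDepth <- sum(failDepth)
  x@stats$removedAltFraction <- sum(failAf)
  x@stats$removedBinomial <- sum(failBinom)
  list(calls = x, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop unless enough variants survived filtering
#'
#' ROH statistics are meaningless on very sparse call sets, so the analysis
#' stops when fewer than `minSurvivingVariants` calls (default 10,000)
#' survive the quality filters. The bound is strict: exactly the threshold
#' proceeds.
#'
#' @param x a filtered [VariantCalls] object.
#' @param params a [RohParams].
#' @return Invisibly `x`; throws a fatal error of class
#'   `autozyg_insufficient_variants` (carrying both counts in its message)
#'   otherwise.
#' @export
assertMinVariants <- function(x, params = rohParams()) {
  nSurv <- length(x@calls)
  if (nSurv < params@minSurvivingVariants)
    .stopFatal("autozyg_insufficient_variants",
               sprintf(paste0("insufficient variants: %d surviving after ",
                              "filtering, %d required"),
                       nSurv, params@minSurvivingVariants))
  invisible(x)
}
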