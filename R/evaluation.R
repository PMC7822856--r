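## Performance metrics: base-pair overlap of a test ROH set against a
## reference ROH set, with gap exclusion and size filtering.

.evalGr <- function(x) {
  gr <- if (is(x, "RohSet")) x@rohs else x
  GenomicRanges::reduce(.normSeqlevels(gr))
}

#' Filter ROHs for performance evaluation
#'
#' Subtracts assembly gap regions (centromeres, telomeres, short arms,
#' heterochromatin) from every ROH, then keeps fragments strictly larger
#' than `minSizeMb` megabases (set `strict = FALSE` for an inclusive
#' bound). Subtraction happens before the size threshold, so a gap-spanning
#' ROH is judged on its usable extent.
#'
#' @param rohs a [RohSet] or `GRanges`.
#' @param minSizeMb size threshold in Mb (typically 1 or 5).
#' @param gaps gap regions as `GRanges` (or NULL for none).
#' @param strict logical; `TRUE` keeps fragments with size > threshold,
#'   `FALSE` size >= threshold.
#' @return A `GRanges` of filtered fragments.
#' @export
filterRohsForEval <- function(rohs, minSizeMb = 1, gaps = NULL,
                              strict = TRUE) {
  gr <- .evalGr(rohs)
  if (!is.null(gaps) && length(gaps) > 0L) {
    u <- .onCommonSeqlevels(gr, GenomicRanges::reduce(gaps))
    gr <- GenomicRanges::setdiff(u$a, u$b)
  }
  w <- GenomicRanges::width(gr)
  thr <- minSizeMb * .MB
  gr[if (strict) w > thr else w >= thr]
}

#' Total base pairs shared by two ROH sets
#'
#' The size in bp of the intersection of the two interval unions —
#' equivalent to intersecting the two sets as BED files and summing the
#' resulting interval sizes.
#'
#' @param a,b [RohSet] or `GRanges` objects.
#' @return Numeric scalar, overlapping base pairs.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("1", IRanges::IRanges(51, 150))
#' overlapBp(a, b)  # 50
overlapBp <- function(a, b) {
  u <- .onCommonSeqlevels(.evalGr(a), .evalGr(b))
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(u$a, u$b))))
}

#' Base-pair sensitivity of a test ROH set
#'
#' Percent of the *filtered* reference covered by the *unfiltered* test
#' set: `100 * overlap(test_all, ref_filtered) / total(ref_filtered)`.
#' Undefined (NA) when the filtered reference is empty.
#'
#' @param testAll the complete (unfiltered) test ROH set.
#' @param refFiltered the reference set after [filterRohsForEval()].
#' @return Percent in `[0, 100]`, or `NA`.
#' @export
rohSensitivity <- function(testAll, refFiltered) {
  ref <- .evalGr(refFiltered)
  tot <- sum(as.numeric(GenomicRanges::width(ref)))
  if (tot == 0) return(NA_real_)
  100 * overlapBp(testAll, ref) / tot
}

#' Base-pair specificity of a test ROH set
#'
#' Percent of the *filtered* test set covered by the *unfiltered*
#' reference: `100 * overlap(test_filtered, ref_all) / total(test_filtered)`.
#' Undefined (NA) when the filtered test set is empty.
#'
#' @param testFiltered the test set after [filterRohsForEval()].
#' @param refAll the complete (unfiltered) reference ROH set.
#' @return Percent in `[0, 100]`, or `NA`.
#' @export
rohSpecificity <- function(testFiltered, refAll) {
  test <- .evalGr(testFiltered)
  tot <- sum(as.numeric(GenomicRanges::width(test)))
  if (tot == 0) return(NA_real_)
  100 * overlapBp(test, refAll) / tot
}

#' Harmonic mean of sensitivity and specificity
#'
#' `F = 2 * sensitivity * specificity / (sensitivity + specificity)`,
#' defined as 0 when both inputs are 0 and NA when either is NA.
#'
#' @param sens,spec percentages.
#' @return Percent in `[0, 100]`.
#' @export
#' @examples
#' fScore(50, 100)  # 66.67
fScore <- function(sens, spec) {
  if (is.na(sens) || is.na(spec)) return(NA_real_)
  if (sens + spec == 0) return(0)
  2 * sens * spec / (sens + spec)
}

#' Evaluate a test ROH set against a reference
#'
#' Computes base-pair sensitivity, specificity and F-score of `test`
#' against `ref`. Following the metric definitions, sensitivity intersects
#' the unfiltered test set with the gap-excluded, size-filtered reference,
#' while specificity intersects the gap-excluded, size-filtered test set
#' with the unfiltered reference.
#'
#' @param test detected ROHs: [RohSet], `GRanges`, or BED path.
#' @param ref reference ROHs (e.g. SNP-array calls): same types.
#' @param gaps assembly gaps: `GRanges`, BED path, or NULL.
#' @param minSizeMb size threshold in Mb for the filtered sets (1 or 5).
#' @param strict strict (`>`) size threshold; see [filterRohsForEval()].
#' @return A [RohEvaluation].
#' @export
evaluateRohs <- function(test, ref, gaps = NULL, minSizeMb = 1,
                         strict = TRUE) {
  asGr <- function(v) if (is.character(v)) loadBed(v) else v
  test <- asGr(test); ref <- asGr(ref); gaps <- asGr(gaps)
  refF <- filterRohsForEval(ref, minSizeMb, gaps, strict)
  testF <- filterRohsForEval(test, minSizeMb, gaps, strict)
  sensOv <- overlapBp(test, refF)
  specOv <- overlapBp(testF, ref)
  refBp <- sum(as.numeric(GenomicRanges::width(refF)))
  testBp <- sum(as.numeric(GenomicRanges::width(testF)))
  sens <- if (refBp == 0) NA_real_ else 100 * sensOv / refBp
  spec <- if (testBp == 0) NA_real_ else 100 * specOv / testBp
  new("RohEvaluation",
      sensitivity = sens, specificity = spec, fScore = fScore(sens, spec),
      refBp = refBp, testBp = testBp,
      sensOverlapBp = sensOv, specOverlapBp = specOv)
}

#' Compare detected ROHs against a planted truth set
#'
#' Convenience wrapper over [evaluateRohs()] with the simulation truth as
#' the reference.
#'
#' @param detected [RohSet], `GRanges` or BED path of detected ROHs.
#' @param truth `GRanges` or BED path of planted segments.
#' @param gaps optional gap regions.
#' @param minSizeMb size threshold for the filtered sets.
#' @param strict strict size threshold (see [filterRohsForEval()]).
#' @return A [RohEvaluation].
#' @export
truthCompare <- function(detected, truth, gaps = NULL, minSizeMb = 1,
                         strict = TRUE) {
  evaluateRohs(detected, truth, gaps = gaps, minSizeMb = minSizeMb,
               strict = strict)
}
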