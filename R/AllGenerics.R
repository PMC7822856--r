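#' @importFrom GenomicRanges granges start end width seqnames
NULL

#' Accessors for autozyg classes
#'
#' Standard accessors: `calls()` returns the variant-call `GRanges` of a
#' [VariantCalls] object, `rohRanges()` the ROH `GRanges` of a [RohSet],
#' `sampleId()` the sample name, `detectionParams()` the [RohParams] of a
#' [RohSet], `filterLog()` the per-stage accounting of a [RohSet], and
#' `nCalls()` / `nRohs()` the element counts.
#'
#' @param x a [VariantCalls] or [RohSet] object.
#' @return See individual descriptions.
#' @name accessors
#' @examples
#' vc <- variantCalls(
#'   chrom = "chr1", pos = c(100, 200), zygosity = c("HOM_ALT", "HET"),
#'   depth = c(20L, 30L), altReads = c(20L, 14L)
#' )
#' nCalls(vc)
#' calls(vc)
NULL

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("rohRanges", function(x) standardGeneric("rohRanges"))

#' @rdname accessors
#' @export
setGeneric("detectionParams", function(x) standardGeneric("detectionParams"))

#' @rdname accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname accessors
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))

#' @rdname accessors
#' @export
setGeneric("nRohs", function(x) standardGeneric("nRohs"))

#' @rdname accessors
#' @export
setMethod("calls", "VariantCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("sampleId", "VariantCalls", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "RohSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("rohRanges", "RohSet", function(x) x@rohs)

#' @rdname accessors
#' @export
setMethod("rohRanges", "GRanges", function(x) x)

#' @rdname accessors
#' @export
setMethod("detectionParams", "RohSet", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("filterLog", "RohSet", function(x) x@log)

#' @rdname accessors
#' @export
setMethod("nCalls", "VariantCalls", function(x) length(x@calls))

#' @rdname accessors
#' @export
setMethod("nRohs", "RohSet", function(x) length(x@rohs))

setMethod("show", "VariantCalls", function(object) {
  gr <- object@calls
  z <- table(factor(mcols(gr)$zygosity, c("HOM_ALT", "HET", "HEMI")))
  cat("VariantCalls for sample '", object@sampleId, "': ",
      length(gr), " calls (", z[["HOM_ALT"]], " hom, ", z[["HET"]],
      " het, ", z[["HEMI"]], " hemi) on ",
      length(unique(as.character(GenomicRanges::seqnames(gr)))),
      " chromosome(s)\n", sep = "")
  st <- object@stats
  if (length(st)) {
    drp <- unlist(st[grepl("^dropped", names(st))])
    if (length(drp) && sum(drp) > 0)
      cat("  dropped during parsing:",
          paste(sprintf("%s=%d", sub("^dropped", "", names(drp)), drp),
                collapse = " "), "\n")
  }
  invisible(object)
})

setMethod("show", "RohSet", function(object) {
  gr <- object@rohs
  cat("RohSet for sample '", object@sampleId, "': ", length(gr),
      " ROH(s), cumulative ", sprintf("%.2f", sum(GenomicRanges::width(gr)) / 1e6),
      " Mb\n", sep = "")
  if (length(gr)) {
    df <- rohTable(object)
    print(utils::head(df, 8))
    if (nrow(df) > 8) cat("  ...", nrow(df) - 8, "more\n")
  }
  invisible(object)
})

setMethod("show", "RohParams", function(object) {
  cat("RohParams:", .paramString(object), "\n")
  invisible(object)
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@input, "calls in,", object@surviving,
      "surviving\n  removed:",
      paste(sprintf("%s=%d", names(object@removed), object@removed),
            collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@repeats), "repeat interval(s),",
      length(object@gaps), "gap interval(s),",
      length(object@chromLengths), "chromosome length(s)\n")
  invisible(object)
})

setMethod("show", "RohEvaluation", function(object) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat("RohEvaluation: sensitivity ", fmt(object@sensitivity),
      ", specificity ", fmt(object@specificity),
      ", F-score ", fmt(object@fScore), "\n", sep = "")
  invisible(object)
})
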