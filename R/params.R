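#' Construct the detection parameter set
#'
#' Returns a [RohParams] object holding the algorithm's tunable parameters
#' with their default values. Defaults correspond to the published
#' command-line options of the method: `--DP 8`, `--minpercalt 0.25`,
#' `--maxpercalt 0.75`, `--binomial 0.000001`, `--window 7`,
#' `--windowthres 5`, `--maxgap 10` (Mb), `--extend 1` (Mb), `--minsize 1`
#' (Mb), `--minvar 25`, `--minperc 88` (%), chromosome X excluded.
#'
#' @param minDepth minimum read depth (reads); calls below are removed.
#' @param minAltFraction,maxAltFraction inclusive allele-balance bounds
#'   applied to heterozygous calls (fraction of alternative reads).
#' @param binomialP exact two-sided binomial p-value threshold; heterozygous
#'   calls with p strictly below are removed.
#' @param minSurvivingVariants the analysis stops (fatal error) when fewer
#'   variants survive the quality filters.
#' @param window sliding-window size in variants.
#' @param windowThres minimum homozygous variants for a window to pass.
#' @param maxGapMb maximum variant-free stretch (Mb) inside an ROH; larger
#'   stretches split the ROH.
#' @param extendMb maximum boundary extension (Mb) after trimming.
#' @param minSizeMb minimum ROH size (Mb), inclusive.
#' @param minVar minimum number of variants per ROH, inclusive.
#' @param minPerc minimum percent homozygous variants per ROH, inclusive.
#' @param includeChrX analyse chromosome X? Hemizygous X calls count as
#'   homozygous; a diploid (female) X is treated as an autosome.
#' @param sex "male", "female" or "auto" (inferred from the X heterozygosity
#'   rate when X is analysed); recorded in the run log.
#' @return A validated [RohParams] object.
#' @export
#' @examples
#' rohParams()
#' rohParams(minSizeMb = 2, includeChrX = TRUE)
rohParams <- function(minDepth = 8,
                      minAltFraction = 0.25,
                      maxAltFraction = 0.75,
                      binomialP = 0.000001,
                      minSurvivingVariants = 10000,
                      window = 7,
                      windowThres = 5,
                      maxGapMb = 10,
                      extendMb = 1,
                      minSizeMb = 1,
                      minVar = 25,
                      minPerc = 88,
                      includeChrX = FALSE,
                      sex = "auto") {
  new("RohParams",
      minDepth = as.integer(minDepth),
      minAltFraction = as.numeric(minAltFraction),
      maxAltFraction = as.numeric(maxAltFraction),
      binomialP = as.numeric(binomialP),
      minSurvivingVariants = as.integer(minSurvivingVariants),
      window = as.integer(window),
      windowThres = as.integer(windowThres),
      maxGapMb = as.numeric(maxGapMb),
      extendMb = as.numeric(extendMb),
      minSizeMb = as.numeric(minSizeMb),
      minVar = as.integer(minVar),
      minPerc = as.numeric(minPerc),
      includeChrX = isTRUE(includeChrX),
      sex = as.character(sex))
}

## One-line parameter echo used in report headers and logs.
.paramString <- function(p) {
  paste0(
    "DP=", p@minDepth,
    " minpercalt=", format(p@minAltFraction),
    " maxpercalt=", format(p@maxAltFraction),
    " binomial=", format(p@binomialP),
    " window=", p@window,
    " windowthres=", p@windowThres,
    " maxgap=", format(p@maxGapMb),
    " extend=", format(p@extendMb),
    " minsize=", format(p@minSizeMb),
    " minvar=", p@minVar,
    " minperc=", format(p@minPerc),
    " chrX=", ifelse(p@includeChrX, "yes", "no"),
    " sex=", p@sex
  )
}
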