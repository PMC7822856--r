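## Seeded generator of exome-like variant calls with planted autozygous
## segments and WES-style genotype noise, plus the companion annotation
## files (truth BED, repeat BED, gap BED, chromosome-length table).

#' Simulation configuration
#'
#' Describes one synthetic exome: chromosome geometry, exon-clustered
#' variant spacing, planted autozygous segments, background genotype
#' composition, a read-depth model, and an allele-skewed false-heterozygous
#' noise model — the artifact class the allele-balance and binomial filters
#' are built to remove.
#'
#' Defaults emulate a consanguineous exome: 22 autosomes of 130 Mb, about
#' 18 variants per Mb clustered into exon-like islands, planted segments
#' summing to 100 Mb of autozygosity, 66% of off-segment variant sites
#' heterozygous (common-variant heterozygote excess), negative-binomial
#' depth around 60x, and false-heterozygous noise whose allele fraction is
#' drawn from a mixture peaked near 0.1 and 0.9 (mapping/calling artifacts
#' are allele-skewed), with a fraction of noise calls instead emitted at
#' low depth.
#'
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @param nChromosomes number of autosomes (`chr1 ... chrN`).
#' @param chromLength length of each chromosome (bp).
#' @param targetDensity average variant sites per Mb.
#' @param plantedSegments `data.frame(chrom, start, end)` of autozygous
#'   segments (1-based inclusive), or NULL for the default 100 Mb profile
#'   (segments of 25, 20, 15, 12, 10, 8, 5, 3, 2 Mb on chr1..chr9).
#' @param backgroundHetRate fraction of off-segment sites heterozygous.
#' @param inRohFalseHetRate fraction of in-segment sites emitted as false
#'   heterozygous calls, in `[0, 0.3]`.
#' @param depthMean,depthDispersion negative-binomial depth model (mu,
#'   size).
#' @param noiseAltShapeLow,noiseAltShapeHigh Beta shape pairs for the low-
#'   and high-skew components of the noise allele-fraction mixture.
#' @param noiseHighWeight probability of the high-skew component.
#' @param noiseLowDepthFrac fraction of noise calls emitted at low depth
#'   (1-7 reads, balanced alleles) instead of skewed allele fraction.
#' @param exonBp,blockBp exon-cluster geometry: each `blockBp` unit holds
#'   at most one exon island of `exonBp` in which its variants cluster.
#' @param gapMb length of the central assembly gap per chromosome (Mb).
#' @param repeatFrac approximate fraction of each chromosome covered by
#'   simulated repeat intervals.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 22L,
                      chromLength = 1.3e8,
                      targetDensity = 18,
                      plantedSegments = NULL,
                      backgroundHetRate = 0.66,
                      inRohFalseHetRate = 0,
                      depthMean = 60,
                      depthDispersion = 8,
                      noiseAltShapeLow = c(2, 18),
                      noiseAltShapeHigh = c(18, 2),
                      noiseHighWeight = 0.5,
                      noiseLowDepthFrac = 0.3,
                      exonBp = 8000,
                      blockBp = 50000,
                      gapMb = 3,
                      repeatFrac = 0.05) {
  if (is.null(plantedSegments)) {
    sizes <- c(25, 20, 15, 12, 10, 8, 5, 3, 2) * .MB
    sizes <- sizes[seq_len(min(length(sizes), nChromosomes))]
    plantedSegments <- data.frame(
      chrom = paste0("chr", seq_along(sizes)),
      start = 8e7,
      end = 8e7 + sizes - 1
    )
  }
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromLength = chromLength, targetDensity = targetDensity,
              plantedSegments = plantedSegments,
              backgroundHetRate = backgroundHetRate,
              inRohFalseHetRate = inRohFalseHetRate,
              depthMean = depthMean, depthDispersion = depthDispersion,
              noiseAltShapeLow = noiseAltShapeLow,
              noiseAltShapeHigh = noiseAltShapeHigh,
              noiseHighWeight = noiseHighWeight,
              noiseLowDepthFrac = noiseLowDepthFrac,
              exonBp = exonBp, blockBp = blockBp,
              gapMb = gapMb, repeatFrac = repeatFrac)
  class(cfg) <- "simConfig"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  seg <- cfg$plantedSegments
  if (nrow(seg)) {
    chroms <- paste0("chr", seq_len(cfg$nChromosomes))
    if (!all(seg$chrom %in% chroms))
      .stopFatal("autozyg_sim_error",
                 "planted segment on a chromosome outside the genome")
    if (any(seg$start < 1) || any(seg$end > cfg$chromLength) ||
        any(seg$end <= seg$start))
      .stopFatal("autozyg_sim_error",
                 "planted segment outside chromosome bounds")
    gr <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(seg$start, seg$end))
    if (!all(GenomicRanges::isDisjoint(gr)))
      .stopFatal("autozyg_sim_error", "planted segments overlap")
  }
  rates <- c(cfg$backgroundHetRate, cfg$inRohFalseHetRate,
             cfg$noiseHighWeight, cfg$noiseLowDepthFrac, cfg$repeatFrac)
  if (any(rates < 0) || any(rates > 1))
    .stopFatal("autozyg_sim_error", "rates must be in [0, 1]")
  if (cfg$inRohFalseHetRate > 0.3)
    .stopFatal("autozyg_sim_error", "inRohFalseHetRate must be <= 0.3")
  invisible(cfg)
}

.simBases <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- sample(b[-1L], n, replace = TRUE)
  swap <- alt == ref
  alt[swap] <- b[match(ref[swap], b) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Generate a synthetic exome with planted autozygous segments
#'
#' Places variant sites in exon-like clusters along each chromosome
#' (leaving a central assembly gap empty), assigns genotypes — homozygous
#' inside planted segments except for a configurable fraction of false
#' heterozygous noise calls; heterozygous with probability
#' `backgroundHetRate` outside — samples read depths and allele counts,
#' and returns the calls plus matching annotation objects. With `dir`
#' given, also writes `sample.vcf`, `truth.bed`, `repeats.bed`, `gaps.bed`
#' and `chrom_lengths.tsv`.
#'
#' Read counts are binomial given depth: near 1 for true homozygous sites,
#' 0.5 for true heterozygous sites, and drawn from the skewed noise model
#' for false heterozygous calls (or emitted at low depth). All randomness
#' derives from `config$seed`; two runs with the same config are
#' byte-identical.
#'
#' @param config a [simConfig()] list.
#' @param dir output directory, or NULL for in-memory only.
#' @param sampleId sample name in the VCF.
#' @return A list: `calls` ([VariantCalls]), `truth` (`GRanges` of planted
#'   segments), `annotation` ([GenomeAnnotation]), `chromLengths`, and
#'   (when `dir` is given) the file `paths`.
#' @export
simulateRohData <- function(config = simConfig(), dir = NULL,
                            sampleId = "SIM001") {
  .validateSimConfig(config)
  .withSeed(config$seed, {
    chroms <- paste0("chr", seq_len(config$nChromosomes))
    chromLengths <- stats::setNames(rep(config$chromLength,
                                        config$nChromosomes), chroms)
    segGr <- GenomicRanges::GRanges(
      config$plantedSegments$chrom,
      IRanges::IRanges(config$plantedSegments$start,
                       config$plantedSegments$end))

    gapHalf <- config$gapMb * .MB / 2
    gapGr <- GenomicRanges::GRanges(
      chroms,
      IRanges::IRanges(start = round(config$chromLength / 2 - gapHalf) + 1,
                       end = round(config$chromLength / 2 + gapHalf)))

    ## exon-clustered site placement: each blockBp unit contributes
    ## Poisson(density * blockBp) sites inside one exon island
    perBlock <- config$targetDensity * config$blockBp / .MB
    posL <- list(); chrL <- list()
    for (ch in chroms) {
      blockStarts <- seq(1, config$chromLength - config$blockBp,
                         by = config$blockBp)
      kk <- stats::rpois(length(blockStarts), perBlock)
      nz <- which(kk > 0L)
      if (length(nz) == 0L) next
      exonOff <- floor(stats::runif(length(nz)) *
                       (config$blockBp - config$exonBp))
      p <- unlist(lapply(seq_along(nz), function(t) {
        es <- blockStarts[nz[t]] + exonOff[t]
        es + floor(stats::runif(kk[nz[t]]) * config$exonBp)
      }))
      p <- sort(unique(p))
      posL[[ch]] <- p
      chrL[[ch]] <- rep(ch, length(p))
    }
    pos <- unlist(posL, use.names = FALSE)
    chrom <- unlist(chrL, use.names = FALSE)

    ## drop sites inside the assembly gap
    inGap <- containsPosition(gapGr, chrom, pos)
    pos <- pos[!inGap]; chrom <- chrom[!inGap]
    n <- length(pos)

    inSeg <- containsPosition(segGr, chrom, pos)
    isNoise <- inSeg & stats::runif(n) < config$inRohFalseHetRate
    isHet <- (!inSeg & stats::runif(n) < config$backgroundHetRate) | isNoise

    depth <- stats::rnbinom(n, mu = config$depthMean,
                            size = config$depthDispersion)

    ## allele fraction model per site class
    afTrue <- ifelse(isHet, 0.5, 0.995)
    lowDepthNoise <- isNoise & stats::runif(n) < config$noiseLowDepthFrac
    skewNoise <- isNoise & !lowDepthNoise
    if (any(skewNoise)) {
      m <- sum(skewNoise)
      hi <- stats::runif(m) < config$noiseHighWeight
      af <- numeric(m)
      af[hi] <- stats::rbeta(sum(hi), config$noiseAltShapeHigh[1L],
                             config$noiseAltShapeHigh[2L])
      af[!hi] <- stats::rbeta(sum(!hi), config$noiseAltShapeLow[1L],
                              config$noiseAltShapeLow[2L])
      afTrue[skewNoise] <- af
    }
    if (any(lowDepthNoise))
      depth[lowDepthNoise] <- 1L + stats::rpois(sum(lowDepthNoise), 2)

    altReads <- stats::rbinom(n, depth, afTrue)
    zyg <- ifelse(isHet, "HET", "HOM_ALT")
    bases <- .simBases(n)

    ## simulated repeat track: random short intervals, merged
    nRep <- round(config$chromLength * config$repeatFrac / 2000)
    repGr <- if (nRep > 0L) {
      st <- unlist(lapply(chroms, function(ch)
        sort(floor(stats::runif(nRep) * (config$chromLength - 4000)) + 1)))
      GenomicRanges::reduce(GenomicRanges::GRanges(
        rep(chroms, each = nRep), IRanges::IRanges(st, width = 2000L)))
    } else GenomicRanges::GRanges()

    calls <- variantCalls(chrom, pos, zyg, depth, altReads,
                          ref = bases$ref, alt = bases$alt,
                          sampleId = sampleId)
    annotation <- genomeAnnotation(repeats = repGr, gaps = gapGr,
                                   chromLengths = chromLengths)
    out <- list(calls = calls, truth = segGr, annotation = annotation,
                chromLengths = chromLengths, config = config)

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(vcf = file.path(dir, "sample.vcf"),
                    truth = file.path(dir, "truth.bed"),
                    repeats = file.path(dir, "repeats.bed"),
                    gaps = file.path(dir, "gaps.bed"),
                    lengths = file.path(dir, "chrom_lengths.tsv"))
      writeVcfCalls(calls, paths$vcf, chromLengths)
      writeBed(segGr, paths$truth)
      writeBed(repGr, paths$repeats)
      writeBed(gapGr, paths$gaps)
      utils::write.table(
        data.frame(names(chromLengths),
                   format(chromLengths, scientific = FALSE, trim = TRUE)),
        paths$lengths, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
      out$paths <- paths
    }
    out
  })
}
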