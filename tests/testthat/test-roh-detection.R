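## Shorthand: calls at fixed spacing with a zygosity pattern string
## (H = homozygous, e = heterozygous).
patternCalls <- function(pattern, chrom = "chr1", start = 1e6,
                         spacing = 1e4) {
  z <- strsplit(pattern, "")[[1]]
  variantCalls(chrom, start + (seq_along(z) - 1) * spacing,
               ifelse(z == "H", "HOM_ALT", "HET"),
               depth = 50L, altReads = ifelse(z == "H", 50L, 25L))
}

test_that("window seeding covers obvious homozygous runs", {
  allHom <- patternCalls(strrep("H", 30))
  cand <- seedWindows(allHom, rohParams())
  expect_equal(length(cand), 1L)
  expect_equal(GenomicRanges::start(cand), 1e6)
  expect_equal(GenomicRanges::end(cand), 1e6 + 29 * 1e4)

  alternating <- patternCalls(strrep("He", 15))
  expect_equal(length(seedWindows(alternating, rohParams())), 0L)

  oneHet <- patternCalls(paste0(strrep("H", 20), "e", strrep("H", 20)))
  cand <- seedWindows(oneHet, rohParams())
  expect_equal(length(cand), 1L)
  expect_equal(GenomicRanges::width(cand), 40 * 1e4 + 1)
})

test_that("window seeding equals brute-force window enumeration", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(5:300, 1)
    pHom <- stats::runif(1, 0.2, 0.95)
    hom <- stats::runif(n) < pHom
    pattern <- paste(ifelse(hom, "H", "e"), collapse = "")
    x <- patternCalls(pattern)
    p <- rohParams()
    cand <- seedWindows(x, p)
    runs <- coverRuns(bruteWindowCover(hom, p@window, p@windowThres))
    pos <- GenomicRanges::start(calls(x))
    expect_equal(GenomicRanges::start(cand), pos[runs[, "from"]])
    expect_equal(GenomicRanges::end(cand), pos[runs[, "to"]])
  }
})

test_that("trimming anchors candidates on homozygous boundaries", {
  x <- patternCalls(paste0("ee", strrep("H", 30), "e"))
  cand <- seedWindows(x, rohParams())
  tr <- trimCandidates(cand, x)
  pos <- GenomicRanges::start(calls(x))
  expect_equal(GenomicRanges::start(tr), pos[3])
  expect_equal(GenomicRanges::end(tr), pos[32])
  ## candidates already anchored are unchanged
  y <- patternCalls(strrep("H", 30))
  cy <- seedWindows(y, rohParams())
  expect_equal(IRanges::ranges(trimCandidates(cy, y)), IRanges::ranges(cy))
  ## a candidate without homozygous members is discarded
  hetOnly <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 2e6))
  allHet <- patternCalls(strrep("e", 10))
  expect_equal(length(trimCandidates(hetOnly, allHet)), 0L)
})

test_that("extension runs to the cap, stops before het calls, merges", {
  ann <- genomeAnnotation(chromLengths = c(chr1 = 1e8))
  p <- rohParams()
  ## lone ROH, no external variants: both ends move exactly 1 Mb
  x <- patternCalls(strrep("H", 30), start = 5e7)
  roh <- trimCandidates(seedWindows(x, p), x)
  ext <- extendRohs(roh, x, ann, p)
  expect_equal(GenomicRanges::start(ext), 5e7 - 1e6)
  expect_equal(GenomicRanges::end(ext), GenomicRanges::end(roh) + 1e6)

  ## external het 200 kb to the right: extension stops just inside it
  hetPos <- GenomicRanges::end(roh) + 2e5
  x2 <- variantCalls(
    "chr1", c(GenomicRanges::start(calls(x)), hetPos),
    c(rep("HOM_ALT", 30), "HET"),
    depth = 50L, altReads = c(rep(50L, 30), 25L))
  ext2 <- extendRohs(roh, x2, ann, p)
  expect_equal(GenomicRanges::end(ext2), hetPos - 1)
  expect_equal(GenomicRanges::start(ext2), 5e7 - 1e6)

  ## two trimmed ROHs 1.5 Mb apart, nothing between: abut after 1 Mb
  ## extension each and merge into one
  aEnd <- 2e7 + 29 * 1e4
  bStart <- aEnd + 1.5e6
  both <- variantCalls(
    "chr1", c(2e7 + (0:29) * 1e4, bStart + (0:29) * 1e4),
    "HOM_ALT", depth = 50L, altReads = 50L)
  rohs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(2e7, bStart), c(aEnd, bStart + 29 * 1e4)))
  merged <- extendRohs(rohs, both, ann, p)
  expect_equal(length(merged), 1L)
  expect_equal(GenomicRanges::start(merged), 2e7 - 1e6)

  ## chromosome end caps extension
  edge <- patternCalls(strrep("H", 30), start = 5e5)
  rohE <- trimCandidates(seedWindows(edge, p), edge)
  extE <- extendRohs(rohE, edge, ann, p)
  expect_equal(GenomicRanges::start(extE), 1)
})

test_that("ROHs split at variant-free stretches beyond the gap limit", {
  p <- rohParams()
  mkRun <- function(startMb, n) (startMb * 1e6) + (seq_len(n) - 1) * 1e4
  ## two variant clusters 11 Mb apart inside one ROH -> split
  pos <- c(mkRun(10, 30), mkRun(10 + 0.3 + 11, 30))
  x <- variantCalls("chr1", pos, "HOM_ALT", depth = 50L, altReads = 50L)
  roh <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(min(pos), max(pos)))
  sp <- splitOnGaps(roh, x, p)
  expect_equal(length(sp), 2L)
  expect_equal(GenomicRanges::end(sp)[1], pos[30])
  expect_equal(GenomicRanges::start(sp)[2], pos[31])

  ## 9 Mb stretch stays intact
  pos2 <- c(mkRun(10, 30), mkRun(10 + 0.3 + 9, 30))
  x2 <- variantCalls("chr1", pos2, "HOM_ALT", depth = 50L, altReads = 50L)
  roh2 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(min(pos2), max(pos2)))
  expect_equal(length(splitOnGaps(roh2, x2, p)), 1L)

  ## two oversized stretches -> three ROHs
  pos3 <- c(mkRun(10, 30), mkRun(22, 30), mkRun(34, 30))
  x3 <- variantCalls("chr1", pos3, "HOM_ALT", depth = 50L, altReads = 50L)
  roh3 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(min(pos3), max(pos3)))
  expect_equal(length(splitOnGaps(roh3, x3, p)), 3L)
})

test_that("final filter enforces size, variant count and homozygosity", {
  mkRoh <- function(sizeBp, nVar, nHom) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1e6 + sizeBp - 1))
    S4Vectors::mcols(gr)$nVariants <- nVar
    S4Vectors::mcols(gr)$nHomozygous <- nHom
    S4Vectors::mcols(gr)$percHomozygous <- 100 * nHom / nVar
    gr
  }
  p <- rohParams()
  expect_equal(length(finalFilter(mkRoh(2e6, 30, 30), p)), 1L)
  expect_equal(length(finalFilter(mkRoh(2e6, 24, 24), p)), 0L)   # minvar 25
  expect_equal(length(finalFilter(mkRoh(2e6, 25, 25), p)), 1L)
  expect_equal(length(finalFilter(mkRoh(1e6, 30, 30), p)), 1L)   # 1 Mb incl.
  expect_equal(length(finalFilter(mkRoh(1e6 - 1, 30, 30), p)), 0L)
  expect_equal(length(finalFilter(mkRoh(2e6, 1000, 880), p)), 1L)  # 88.0%
  expect_equal(length(finalFilter(mkRoh(2e6, 1000, 879), p)), 0L)  # 87.9%
})

test_that("planted segments are recovered whole, with and without noise", {
  sim <- smallSim(seed = 42)
  res <- detectRohs(sim$calls, sim$annotation, smallParams())
  expect_equal(nRohs(res), 2L)
  ov <- GenomicRanges::countOverlaps(sim$truth, rohRanges(res))
  expect_equal(unname(ov), c(1L, 1L))
  ## each planted segment is covered >= 95%
  for (i in seq_along(sim$truth)) {
    cov <- overlapBp(sim$truth[i], rohRanges(res))
    expect_gte(cov / GenomicRanges::width(sim$truth)[i], 0.95)
  }

  ## 5% false-het in-segment noise with skewed allele balance: same
  ## single-ROH-per-segment result, no fragmentation
  simN <- smallSim(seed = 42, noise = 0.05)
  resN <- detectRohs(simN$calls, simN$annotation, smallParams())
  ovN <- GenomicRanges::countOverlaps(simN$truth, rohRanges(resN))
  expect_equal(unname(ovN), c(1L, 1L))
  expect_equal(nRohs(resN), 2L)
})

test_that("no homozygous input yields no ROHs; detection is deterministic", {
  allHet <- patternCalls(strrep("e", 200))
  ann <- genomeAnnotation(chromLengths = c(chr1 = 1e8))
  expect_equal(nRohs(detectRohs(allHet, ann, smallParams())), 0L)

  sim <- smallSim(seed = 9, noise = 0.08)
  r1 <- detectRohs(sim$calls, sim$annotation, smallParams())
  r2 <- detectRohs(sim$calls, sim$annotation, smallParams())
  expect_identical(rohTable(r1), rohTable(r2))
})

test_that("reported ROHs are disjoint, sorted and satisfy the thresholds", {
  sim <- smallSim(seed = 13, noise = 0.1)
  p <- smallParams()
  res <- detectRohs(sim$calls, sim$annotation, p)
  gr <- rohRanges(res)
  expect_true(all(GenomicRanges::isDisjoint(gr)))
  o <- order(as.integer(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  expect_equal(o, seq_along(gr))
  expect_true(all(GenomicRanges::width(gr) >= p@minSizeMb * 1e6))
  expect_true(all(S4Vectors::mcols(gr)$nVariants >= p@minVar))
  expect_true(all(S4Vectors::mcols(gr)$percHomozygous >= p@minPerc - 1e-9))
})

test_that("tightening final thresholds never adds ROHs", {
  sim <- smallSim(seed = 21, noise = 0.1)
  base <- nRohs(detectRohs(sim$calls, sim$annotation, smallParams()))
  for (args in list(list(minPerc = 95), list(minVar = 100),
                    list(minSizeMb = 5), list(minPerc = 99.5),
                    list(minSizeMb = 15))) {
    n <- nRohs(detectRohs(sim$calls, sim$annotation,
                          do.call(smallParams, args)))
    expect_lte(n, base)
  }
})

test_that("hemizygous X calls count as homozygous for male samples", {
  xPos <- 1e6 + (0:39) * 1e4
  hemi <- variantCalls("chrX", xPos, "HEMI", depth = 30L, altReads = 30L)
  ann <- genomeAnnotation(chromLengths = c(chrX = 1e8))
  ## excluded by default
  res0 <- detectRohs(hemi, ann, smallParams())
  expect_equal(nRohs(res0), 0L)
  resX <- detectRohs(hemi, ann, smallParams(includeChrX = TRUE))
  expect_equal(nRohs(resX), 1L)
  expect_equal(filterLog(resX)$sexUsed, "male")
  ## diploid X with many hets behaves as an autosome (no ROH here)
  dip <- variantCalls("chrX", xPos, rep(c("HET", "HOM_ALT"), 20),
                      depth = 30L, altReads = rep(c(15L, 30L), 20))
  resD <- detectRohs(dip, ann, smallParams(includeChrX = TRUE))
  expect_equal(filterLog(resD)$sexUsed, "female")
  expect_equal(nRohs(resD), 0L)
})
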