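test_that("exact binomial p matches hand-derivable cases", {
  expect_equal(binomialTwoSidedP(10, 20), 1.0)
  ## n = 3: pmf (1/8, 3/8, 3/8, 1/8); outcomes no more probable than k = 0
  ## are {0, 3}, so p = 1/4
  expect_equal(binomialTwoSidedP(0, 3), 0.25)
  expect_lt(binomialTwoSidedP(90, 300), 1e-6)
  expect_gt(binomialTwoSidedP(70, 200), 1e-6)
})

test_that("binomial p is symmetric and agrees with independent oracles", {
  for (n in c(1, 2, 3, 7, 20, 45)) {
    for (k in 0:n) {
      p <- binomialTwoSidedP(k, n)
      expect_equal(p, binomialTwoSidedP(n - k, n))
      expect_equal(p, bruteBinomTwoSided(k, n), tolerance = 1e-12)
      expect_equal(p, stats::binom.test(k, n, 0.5)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("repeat-region variants are removed, identity on empty set", {
  x <- variantCalls("chr1", c(100L, 5000L, 9000L), "HOM_ALT",
                    depth = 20L, altReads = 20L)
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 6000))
  y <- removeRepeatVariants(x, reps)
  expect_equal(GenomicRanges::start(calls(y)), c(100L, 9000L))
  expect_equal(y@stats$removedRepeat, 1L)
  z <- removeRepeatVariants(x, GenomicRanges::GRanges())
  expect_equal(nCalls(z), 3L)
  allIn <- removeRepeatVariants(
    x, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e4)))
  expect_equal(nCalls(allIn), 0L)
})

test_that("quality filter applies depth to all calls, balance to hets only", {
  x <- variantCalls(
    "chr1", pos = 1:6 * 100L,
    zygosity = c("HET", "HET", "HOM_ALT", "HOM_ALT", "HEMI", "HET"),
    depth = c(20L, 40L, 7L, 8L, 8L, 300L),
    altReads = c(11L, 8L, 7L, 8L, 8L, 90L))
  res <- qualityFilter(x, rohParams())
  kept <- GenomicRanges::start(calls(res$calls))
  ## kept: HET 11/20 (af 0.55), HOM depth 8, HEMI depth 8
  ## removed: HET af 0.2, HOM depth 7, HET 90/300 binomial
  expect_equal(kept, c(100L, 400L, 500L))
  expect_equal(unname(res$report@removed[c("depth", "alt_fraction",
                                           "binomial")]),
               c(1L, 1L, 1L))
})

test_that("allele-balance bounds are inclusive at 0.25 and 0.75", {
  x <- variantCalls("chr1", c(100L, 200L, 300L, 400L), "HET",
                    depth = 100L, altReads = c(25L, 75L, 24L, 76L))
  res <- qualityFilter(x, rohParams(binomialP = 1e-30))
  expect_equal(GenomicRanges::start(calls(res$calls)), c(100L, 200L))
})

test_that("filter counts are conserved and filtering is idempotent", {
  sim <- smallSim(seed = 5, noise = 0.1)
  x <- removeRepeatVariants(sim$calls, sim$annotation@repeats)
  res <- qualityFilter(x, rohParams())
  rep <- res$report
  expect_equal(sum(rep@removed) + rep@surviving, rep@input)
  again <- qualityFilter(res$calls, rohParams())
  expect_equal(nCalls(again$calls), nCalls(res$calls))
  expect_equal(sum(again$report@removed[c("depth", "alt_fraction",
                                          "binomial")]), 0L)
})

test_that("surviving set equals an independent predicate, any filter order", {
  sim <- smallSim(seed = 6, noise = 0.1)
  x <- sim$calls
  p <- rohParams()
  res <- qualityFilter(x, p)
  gr <- calls(x)
  z <- as.character(mcols(gr)$zygosity)
  af <- mcols(gr)$altFraction
  dp <- mcols(gr)$depth
  ar <- mcols(gr)$altReads
  ## order-free re-derivation of the survival predicate
  binomOk <- rep(TRUE, length(gr))
  hets <- which(z == "HET" & !is.na(ar) & dp > 0)
  binomOk[hets] <- binomialTwoSidedP(ar[hets], dp[hets]) >= p@binomialP
  keep <- dp >= p@minDepth &
    (z != "HET" | (!is.na(af) & af >= p@minAltFraction &
                   af <= p@maxAltFraction & binomOk))
  expect_equal(GenomicRanges::start(calls(res$calls)),
               GenomicRanges::start(gr)[keep])
})

test_that("raising the depth threshold never recovers variants", {
  sim <- smallSim(seed = 7, noise = 0.05)
  counts <- vapply(c(0, 4, 8, 15, 30), function(d) {
    nCalls(qualityFilter(sim$calls, rohParams(minDepth = d))$calls)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("analysis stops below the minimum surviving-variant count", {
  mk <- function(n) variantCalls("chr1", seq_len(n), "HOM_ALT",
                                 depth = 20L, altReads = 20L)
  expect_error(assertMinVariants(mk(9999), rohParams()),
               "9999.*10000", class = "autozyg_insufficient_variants")
  expect_silent(assertMinVariants(mk(10000), rohParams()))
  expect_silent(assertMinVariants(mk(3), rohParams(minSurvivingVariants = 0)))
})
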