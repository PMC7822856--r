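test_that("genotype, depth and allele fraction map from GT/AD fields", {
  vcf <- writeVcfFixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t1/1:0,17:17",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:9,11:20",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t0|1:10,10:20",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT:AD:DP\t./.:5,5:10"
  ))
  expect_warning(x <- readVcfCalls(vcf), "missing genotype")
  gr <- calls(x)
  expect_equal(length(gr), 3L)
  expect_equal(as.character(mcols(gr)$zygosity),
               c("HOM_ALT", "HET", "HET"))
  expect_equal(mcols(gr)$depth, c(17L, 20L, 20L))
  expect_equal(mcols(gr)$altFraction, c(1.0, 0.55, 0.5))
  expect_equal(x@stats$droppedMissing, 1L)
})

test_that("hemizygous, hom-ref, half-missing and symbolic records", {
  vcf <- writeVcfFixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t1:2,18:20",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/0:20,0:20",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t./1:9,11:20",
    "chr1\t400\t.\tT\t<DEL>\t.\tPASS\t.\tGT:AD:DP\t0/1:9,11:20"
  ))
  expect_warning(x <- readVcfCalls(vcf))
  gr <- calls(x)
  expect_equal(length(gr), 1L)
  expect_equal(as.character(mcols(gr)$zygosity), "HEMI")
  expect_equal(x@stats$droppedHomRef, 1L)
  expect_equal(x@stats$droppedMissing, 1L)
  expect_equal(x@stats$droppedSymbolic, 1L)
})

test_that("multiallelic records decompose per alternative allele", {
  vcf <- writeVcfFixture(c(
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP\t1/2:2,9,9:20",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT:AD:DP\t2/2:1,0,19:20"
  ))
  x <- readVcfCalls(vcf)
  gr <- calls(x)
  expect_equal(length(gr), 3L)
  het <- gr[GenomicRanges::start(gr) == 100]
  expect_equal(as.character(mcols(het)$zygosity), c("HET", "HET"))
  expect_setequal(mcols(het)$alt, c("G", "T"))
  expect_equal(mcols(het)$altFraction, c(9 / 20, 9 / 20))
  hom <- gr[GenomicRanges::start(gr) == 200]
  expect_equal(as.character(mcols(hom)$zygosity), "HOM_ALT")
  expect_equal(mcols(hom)$alt, "G")
  expect_equal(mcols(hom)$altReads, 19L)
})

test_that("DP4 strand counts supply depth and alt fraction", {
  vcf <- writeVcfFixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tDP4=5,5,5,5\tGT\t0/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\tDP4=1,1,9,9\tGT\t1/1"
  ), formats = "GT", infoDp4 = TRUE)
  x <- readVcfCalls(vcf)
  gr <- calls(x)
  expect_equal(mcols(gr)$depth, c(20L, 20L))
  expect_equal(mcols(gr)$altFraction, c(0.5, 0.9))
})

test_that("computeAltFraction handles AD, DP4 and the degenerate case", {
  expect_equal(computeAltFraction(c(9, 11)), 0.55)
  expect_equal(computeAltFraction(c(5, 5, 5, 5)), 0.5)
  expect_true(is.na(computeAltFraction(c(0, 0))))
  expect_error(computeAltFraction(c(1, 2, 3)), "length")
})

test_that("unusable VCFs fail fast, absent samples are fatal", {
  noGt <- writeVcfFixture(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tAD:DP\t9,11:20",
    formats = c("AD", "DP"))
  expect_error(readVcfCalls(noGt), "no GT", class = "autozyg_unusable_vcf")

  noAd <- writeVcfFixture(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:20",
    formats = c("GT", "DP"))
  expect_error(readVcfCalls(noAd), "neither AD nor DP4",
               class = "autozyg_unusable_vcf")

  multi <- writeVcfFixture(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:9,11:20\t1/1:0,15:15",
    samples = c("S1", "S2"))
  expect_error(readVcfCalls(multi, sample = "S9"), "not present",
               class = "autozyg_unusable_vcf")
  expect_error(readVcfCalls(multi), "choose one of",
               class = "autozyg_unusable_vcf")
  x2 <- readVcfCalls(multi, sample = "S2")
  expect_equal(sampleId(x2), "S2")
  expect_equal(mcols(calls(x2))$depth, 15L)
})

test_that("write -> read round trip preserves the call table", {
  x <- variantCalls(
    chrom = rep(c("chr1", "chr2"), c(3, 2)),
    pos = c(100L, 500L, 900L, 150L, 700L),
    zygosity = c("HOM_ALT", "HET", "HOM_ALT", "HEMI", "HET"),
    depth = c(17L, 20L, 30L, 12L, 25L),
    altReads = c(17L, 11L, 29L, 12L, 12L),
    sampleId = "RT1")
  path <- tempfile(fileext = ".vcf")
  writeVcfCalls(x, path, chromLengths = c(chr1 = 1e6, chr2 = 1e6))
  y <- readVcfCalls(path)
  a <- calls(x); b <- calls(y)
  expect_equal(as.character(GenomicRanges::seqnames(b)),
               as.character(GenomicRanges::seqnames(a)))
  expect_equal(GenomicRanges::start(b), GenomicRanges::start(a))
  expect_equal(as.character(mcols(b)$zygosity),
               as.character(mcols(a)$zygosity))
  expect_equal(mcols(b)$depth, mcols(a)$depth)
  expect_equal(sampleId(y), "RT1")
})

test_that("duplicate records collapse and parsing keeps positional order", {
  vcf <- writeVcfFixture(c(
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:9,11:20",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t1/1:0,17:17",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t1/1:0,17:17"
  ))
  x <- readVcfCalls(vcf)
  expect_equal(GenomicRanges::start(calls(x)), c(100L, 200L))
  expect_equal(x@stats$duplicatesRemoved, 1L)
})
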