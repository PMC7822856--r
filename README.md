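# autozyg

Autozygosity mapping — the detection of runs of homozygosity (ROHs) —
directly from VCF genotype calls produced by standard short-read variant
callers (GATK HaplotypeCaller, samtools/bcftools, Strelka, ...).

## The problem

In the offspring of consanguineous unions, recessive disease mutations
almost always lie inside long runs of homozygosity: chromosomal segments
inherited identical-by-descent through both parents. Locating those
segments ("homozygosity mapping") narrows the search space for causal
variants dramatically. SNP arrays call genotypes accurately enough that
classical tools work well on them, but exome sequencing — today's routine
assay — produces sparse, exon-clustered variant sites contaminated with a
few percent of false heterozygous calls. A single false heterozygote inside
a true ROH fragments it or hides it entirely, so array-era window methods
underperform badly on exomes.

`autozyg` addresses this with aggressive variant-level cleaning before
segmentation. False heterozygous calls are recognizable: they tend to have
low coverage or an allele balance far from the 1:1 expected of a true
heterozygote. A call with `a` alternative reads out of `n` is kept as
heterozygous only if

- depth `n ≥ DP` (default 8),
- allele balance `a/n ∈ [0.25, 0.75]` (inclusive), and
- the exact two-sided binomial test of `a` successes in `n` trials at
  `p₀ = 0.5` gives `p ≥ 10⁻⁶`,

and any call inside a UCSC-style repeat region is discarded. ROHs are then
seeded by a sliding window of 7 variants requiring ≥ 5 homozygous calls,
trimmed to homozygous boundaries, extended outward by up to 1 Mb (stopping
at the nearest surviving heterozygous call), split wherever more than 10 Mb
separates consecutive variants, and finally filtered to size ≥ 1 Mb,
≥ 25 variants and ≥ 88 % homozygous calls. Hemizygous calls on a male X are
treated as homozygous; a female X is treated as an autosome.

Detected ROH sets can be scored against a reference set (e.g. SNP-array
calls, or the planted truth of a simulation) by base-pair overlap:

    sensitivity (%) = overlap(test_all, ref_filtered) / total(ref_filtered)
    specificity (%) = overlap(test_filtered, ref_all) / total(test_filtered)
    F-score        = 2 · sens · spec / (sens + spec)

where "filtered" removes assembly gap regions (centromeres, telomeres,
short arms, heterochromatin) and keeps fragments larger than 1 or 5 Mb.

## Worked example

Simulate a small genome (3 chromosomes × 60 Mb) with two planted 10 Mb
autozygous segments and 5 % false-heterozygous noise inside them, then
detect and score:

```r
library(autozyg)

cfg <- simConfig(seed = 7, nChromosomes = 3, chromLength = 6e7,
                 plantedSegments = data.frame(chrom = c("chr1", "chr2"),
                                              start = c(1e7, 3.5e7),
                                              end   = c(2e7 - 1, 4.5e7 - 1)),
                 inRohFalseHetRate = 0.05)
sim <- simulateRohData(cfg, dir = "simdata")

x   <- readVcfCalls(sim$paths$vcf)
ann <- genomeAnnotation(repeats = sim$paths$repeats, gaps = sim$paths$gaps,
                        chromLengths = sim$paths$lengths)
res <- detectRohs(x, ann, rohParams(minSurvivingVariants = 0))
res
#> RohSet for sample 'SIM001': 2 ROH(s), cumulative 20.40 Mb
#>   chrom    start      end  size_bp n_variants perc_homozygosity
#> 1  chr1  9932941 20033644 10100704        163            100.00
#> 2  chr2 34737564 45039861 10302298        163             98.77

filterLog(res)$report
#> FilterReport: 3153 calls in, 2981 surviving
#>   removed: repeat=157 depth=4 alt_fraction=11 binomial=0 missing=0

truthCompare(res, loadBed(sim$paths$truth), gaps = ann@gaps)
#> RohEvaluation: sensitivity 100.00%, specificity 98.02%, F-score 99.00%
```

Both planted segments come back as exactly one ROH each — the noise calls
fall to the allele-balance and binomial filters instead of fragmenting the
segments. (`minSurvivingVariants` is lowered because this toy genome has
only ~3,000 variants; real exomes clear the default 10,000-variant floor.)
`writeRohTable()` writes the table above as TSV + BED with a full parameter
echo, `plotRohs()` draws the per-chromosome ideogram, and
`annotatePanel()` marks which genes of a panel fall inside ROHs.

A command-line wrapper with the classical flag names
(`--DP`, `--minpercalt`, `--maxpercalt`, `--binomial`, `--window`,
`--windowthres`, `--maxgap`, `--extend`, `--minsize`, `--minvar`,
`--minperc`, `--chrX`) is installed at `inst/scripts/autozyg`:

```sh
Rscript inst/scripts/autozyg detect --vcf sample.vcf \
    --repeats repeats.bed --lengths chrom_lengths.tsv --out-prefix patient1
Rscript inst/scripts/autozyg evaluate --test patient1.rohs.bed \
    --ref array.bed --gaps gaps.bed --min-size 1
```

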