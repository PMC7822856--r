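---
title: "Methods: ROH detection from noisy VCF genotypes"
author: "autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection from noisy VCF genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The model

`autozyg` treats autozygosity mapping as a two-stage problem: first decide,
call by call, which variant genotypes can be trusted; then segment the
trusted calls into runs of homozygosity (ROHs).

The central assumption is about how exome genotyping fails. A true
heterozygote carries both alleles at a 1:1 ratio, so its alternative-read
fraction at depth $n$ is approximately $\mathrm{Binomial}(n, 0.5)/n$. The
false heterozygous calls that plague exome data — mismapped reads,
reference bias, paralogous capture — do not obey this law: their allele
balance clusters far from 0.5, or they ride on a handful of reads.
Filtering on depth, allele balance, and an exact binomial test therefore
removes predominantly artifactual heterozygotes while leaving real ones
untouched. This matters because the dominant failure mode of window-based
ROH callers on exomes is *fragmentation*: one false heterozygote inside a
long autozygous segment splits it, and a handful hide it completely.

### Variant-level filter

For a call with $a$ alternative reads out of $n$:

* depth: keep iff $n \ge \texttt{DP}$ (default 8, inclusive — a call at
  exactly 8 reads survives);
* allele balance (heterozygous calls only):
  $a/n \in [\texttt{minpercalt}, \texttt{maxpercalt}]$, default
  $[0.25, 0.75]$, both bounds inclusive;
* binomial (heterozygous calls only): the exact two-sided p-value of $a$
  successes in $n$ trials at $p_0 = 0.5$ must satisfy
  $p \ge \texttt{binomial}$ (default $10^{-6}$; removal is strict,
  $p < 10^{-6}$).

Homozygous and hemizygous calls face only the depth criterion, and calls
inside a user-supplied repeat track are removed outright. The two-sided
p-value uses the minimum-likelihood definition — the sum of the
probabilities of all outcomes no more probable than the observed one —
computed by summation of the binomial pmf, with a $1 + 10^{-7}$ relative
tolerance on the tie comparison to keep floating-point dust from flipping
outcome inclusion at symmetric counts. A one-sided variant of the test is
available as an option. When fewer than 10,000 variants survive (strictly
fewer; exactly 10,000 proceeds), the analysis stops with an error rather
than report ROH statistics from data too sparse to support them.

Filters are applied in the fixed order repeats → depth → allele fraction →
binomial. Because each criterion is evaluated per call, the surviving set
is order-independent; only the per-reason removal counts in the
`FilterReport` depend on the order, and the test suite asserts exactly
that.

### Segmentation

On the filtered calls of each chromosome:

1. **Seeding.** A window of `window` consecutive variants (default 7)
   slides one variant at a time; it passes when it holds at least
   `windowthres` (default 5) homozygous calls. A variant is *covered* when
   it lies in at least one passing window, and candidates are maximal runs
   of covered variants, spanning from the first to the last covered
   variant's position. This inclusive union-of-windows rule also resolves
   tie handling between adjacent candidates: overlapping coverage simply
   merges.
2. **Trimming.** Candidate boundaries move inward to the outermost
   homozygous calls, so no reported ROH begins or ends on a heterozygote.
3. **Extension.** Each boundary then moves outward by up to `extend`
   (default 1 Mb), stopping early at the chromosome end or just inside the
   nearest surviving heterozygous call. The obstruction rule is our
   resolution of an otherwise underdetermined step: without it, extension
   would re-absorb the heterozygotes trimming just removed. ROHs that
   overlap or abut after extension are merged and their statistics
   recomputed.
4. **Gap splitting.** Where consecutive member variants lie more than
   `maxgap` (default 10 Mb) apart, the ROH splits at those variants'
   positions and the empty stretch belongs to neither part. Distances are
   measured between surviving variants, not raw VCF records, since the
   filtered table is what the detector sees.
5. **Final filter.** Keep an ROH iff size $\ge$ `minsize` (default 1 Mb),
   variant count $\ge$ `minvar` (default 25) and percent homozygous calls
   $\ge$ `minperc` (default 88%), all inclusive. The homozygosity
   percentage is computed over all surviving variants inside the ROH's
   final coordinates.

Chromosome X is excluded by default. When requested, hemizygous calls
count as homozygous — the male-X rule — while a diploid female X behaves
as an autosome. Since diploid genotypes already carry their zygosity, the
`sex` parameter does not alter the genotype mapping; `sex = "auto"` infers
the label (X heterozygosity below 5% ⇒ male) and records it in the run
log for reporting. Chromosome Y and the mitochondrial contig are never
analysed.

### Evaluation metrics

Against a reference ROH set (SNP-array calls, or a simulation truth set):

$$\mathrm{sensitivity} = 100 \cdot
  \frac{|\,\mathrm{test}_{\mathrm{all}} \cap \mathrm{ref}_{\mathrm{filtered}}\,|}
       {|\,\mathrm{ref}_{\mathrm{filtered}}\,|}, \qquad
  \mathrm{specificity} = 100 \cdot
  \frac{|\,\mathrm{test}_{\mathrm{filtered}} \cap \mathrm{ref}_{\mathrm{all}}\,|}
       {|\,\mathrm{test}_{\mathrm{filtered}}\,|},$$

with $|\cdot|$ in base pairs and the F-score their harmonic mean. Note the
deliberate asymmetry: each ratio intersects one *unfiltered* set with one
*filtered* set. "Filtered" subtracts assembly gap regions and keeps
fragments larger than 1 or 5 Mb. Two choices here were genuinely open and
are therefore parameters: gaps are subtracted *before* the size threshold
(a gap-spanning ROH should be judged on its usable extent), and "larger
than" is read strictly (`strict = FALSE` switches to inclusive). Both
behaviours are covered by tests.

## VCF interpretation choices

Published descriptions of ROH callers rarely pin down VCF dialect
handling, so the reader deserves an explicit list:

* zygosity from GT: two identical non-reference alleles ⇒ homozygous; two
  different alleles (including `1/2`) ⇒ heterozygous; a single
  non-reference allele ⇒ hemizygous; any missing allele (`./.`, `./1`) ⇒
  dropped with a counted warning;
* homozygous-reference records are dropped: the algorithm is defined over
  variant sites, and single-sample VCFs do not normally emit them;
* multiallelic records are decomposed per alternative allele named by the
  genotype, with per-allele AD read counts;
* depth precedence AD sum → DP4 sum → DP, configurable; heterozygous calls
  whose source yields no per-allele count (DP only) have undefined allele
  fraction and are removed by the balance filter;
* non-ACGT (symbolic/structural) alternative alleles are skipped with a
  warning; `chr1` and `1` naming styles are reconciled internally and the
  input's convention is kept on output.

Intervals are held as `GRanges` (1-based, closed) throughout; the
conversion to and from BED's 0-based half-open convention happens only in
`loadBed()` / `writeBed()`.

## What the simulator emulates — and what it does not

`simConfig()` / `simulateRohData()` generate the test bed the package is
validated on. Emulated features, with defaults chosen once to resemble a
consanguineous exome: 22 autosomes of 130 Mb giving an exome-scale ~50,000
variant calls at ~18 sites/Mb; sites clustered into exon-like islands
(8 kb islands in 50 kb blocks) so that large variant-free stretches exist;
a 3 Mb central assembly gap and a ~5% repeat track per chromosome; planted
autozygous segments totalling 100 Mb (25–2 Mb, within the cumulative-ROH
range reported for consanguineous patients); 66% heterozygous calls at
off-segment sites (common variants are enriched for heterozygotes);
negative-binomial depth with mean 60 and dispersion 8; and false
heterozygous noise inside planted segments at a configurable rate up to
30% — the documented exome noise range — with allele fractions drawn from
a Beta mixture peaked near 0.1 and 0.9, a modelling choice (not an
empirical claim) reflecting that mapping and calling artifacts are
allele-skewed, plus a fraction of noise emitted at low depth instead. All
randomness flows from one seed; identical configurations produce
byte-identical VCFs.

Not emulated: linkage disequilibrium and haplotype structure, real capture
designs, indel/complex alleles, batch effects between callers, and
population-level allele-frequency structure. Passing the planted-recovery
suite therefore demonstrates that the detector withstands allele-skewed
genotype noise at realistic densities — not that its numbers transfer
verbatim to any particular cohort, reference genome or capture kit.

## Problem sizes and numerical details

The test suite verifies the binomial p-value exhaustively against an
independent pmf-summation oracle for all $n \le 200$, the window seeding
against a brute-force window enumerator on 1,000 random tables of up to
500 variants, and the base-pair overlap against per-base counting on
random instances with coordinates up to $10^5$. Planted-segment recovery
runs at the full default scale (~50,000 calls) at 0%, 5% and 10% noise;
module-level tests use a reduced 3-chromosome genome for speed, lowering
the `minSurvivingVariants` floor accordingly (the floor itself is tested
separately at its 10,000 boundary). Comparisons of the homozygosity
percentage against `minperc` allow a $10^{-9}$ absolute slack so that
ratios like $100 \cdot 22/25$ compare as intended at the 88% boundary.

## Known limitations

* ROHs caused by hemizygous deletions or uniparental disomy are reported
  as ordinary ROHs; the package does not classify them.
* The detector is a deterministic rule set, not an HMM; there is no
  per-ROH posterior or quality score beyond the reported statistics.
* Repeat and gap tracks are inputs. Results depend on which UCSC track
  (e.g. RepeatMasker vs. simple repeats) the user exports; the package
  deliberately accepts any BED.
* gVCFs, structural-variant records and allele-frequency-aware priors are
  out of scope.
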