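Package: autozyg
Title: Autozygosity Mapping and Runs of Homozygosity from VCF Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROHs) directly from single- or
    multi-sample VCF files produced by standard short-read variant callers.
    Variant calls are first screened with depth, allele-balance and exact
    binomial criteria that remove the false heterozygous calls typical of
    exome sequencing, then ROHs are located with a sliding-window scan,
    trimmed, extended, split at large variant-free stretches and filtered
    on size, variant count and percent homozygosity. The package also
    provides base-pair overlap metrics (sensitivity, specificity, F-score)
    against a reference ROH set, per-sample tabular, BED and graphical
    reports with gene-panel annotation, and a seeded generator of
    exome-like VCFs with planted autozygous segments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, VariantDetection, SNP, Sequencing
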