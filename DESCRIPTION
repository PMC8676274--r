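Package: breedvar
Title: Breed-Stratified Summary Statistics and Screens for Multi-Sample
    Variant Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and interrogating population-scale variant
    catalogs from multi-sample VCF files, motivated by whole-genome
    sequencing surveys of domestic horse breeds. Provides two-caller site
    concordance (intersection and union), cohort descriptive statistics
    (transition/transversion and heterozygous/non-reference-homozygous
    ratios, missingness, minor-allele-frequency spectra, singletons),
    depth-of-coverage-adjusted estimated marginal means by breed,
    breed-stratified allele-frequency discrepancy screens, screens for
    no-homozygote and present-in-all variant classes, a fixed-window
    variant-density scan, and closed-form detection-power arithmetic.
    A synthetic multi-breed diploid cohort generator (neutral
    allele-frequency spectrum, Balding-Nichols drift, Hardy-Weinberg
    genotypes, depth-dependent missingness, injected truth classes) makes
    every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
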