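Package: nonaddscan
Title: Two-Step Mixed-Model Genome Scan for Non-Additive Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome association scans for non-additive (dominance,
    recessive, overdominance) marker effects on continuous traits in
    structured populations, using an efficient two-step mixed-model
    approach: a single REML fit of the null animal model with a genomic
    relationship matrix, followed by fast per-marker score tests of the
    four genotype codings against the frozen null covariance. Includes
    genomic-control inflation adjustment, Bonferroni thresholding,
    composite linkage-disequilibrium reporting, PLINK text genotype
    input/output, and a synthetic-data generator that emulates paternal
    half-sib family structure with planted quantitative trait loci for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
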