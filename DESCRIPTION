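Package: bitterhap
Title: Bitter-Taste Receptor Haplotypes, Psychophysics and Receptor Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links genetic variation in the human TAS2R bitter-taste receptor
    family (coding SNPs, within-gene haplotypes, whole-gene deletions and
    long-range haplotype blocks) to bitter-taste psychophysics and in-vitro
    receptor pharmacology. Provides a synthetic cohort generator emulating a
    48-subject sensory-genetics study design; EM haplotype phasing at gene and
    block scope with copy-number aware genotypes; multi-allelic linkage
    disequilibrium (D', r-squared) and four-gamete haplotype block partitions;
    maximum-likelihood psychometric fits to 4-AFC detection and yes/no
    recognition series with Peirce outlier rejection and labeled-magnitude
    intensity inversion; mixed-model genotype-phenotype scans with
    permutation-based experiment-wide thresholds; three-step fluorescence
    correction, activation-threshold calls and Hill dose-response fits for
    calcium-imaging plates; and integration logic classifying loci as causal,
    linked passengers or masked by linkage phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
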