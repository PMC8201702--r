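Package: divselgwas
Title: Pedigree-Based GWAS and Allele-Frequency Trajectories in Divergent
    Selection Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing divergent selection experiments in livestock:
    a forward-in-time simulator of a two-line truncation-selection design,
    genotype quality control, prediction of offspring genotypes as parental
    averages, pedigree numerator relationship matrices, single-marker linear
    mixed-model association with genomic control, Bonferroni thresholds based
    on the effective number of independent tests, assembly of significant
    1-Mb windows into QTL regions, and classification of allele-frequency
    trajectories across generations against Wright-Fisher drift baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
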