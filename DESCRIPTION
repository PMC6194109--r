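Package: ystrpop
Title: Y-STR Population Genetics, Forensic Statistics and Haplotype Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Y-chromosomal short tandem repeat (Y-STR)
    haplotype panels such as PowerPlex Y23: cohort input/output with
    microvariant-aware allele handling and quality-control filters, locus and
    haplotype diversity with the standard forensic parameters (genetic
    diversity, haplotype diversity, discrimination capacity, combined match
    probability), R_ST-based analysis of molecular variance with permutation
    tests, pairwise population distances (R_ST, Nei's standard distance),
    principal coordinates analysis and Sammon multidimensional scaling,
    Mantel tests of geography against genetics, a naive-Bayes haplogroup
    classifier with score and posterior thresholds, minimum-spanning and
    median-joining haplotype networks with variance-binned locus weights, and
    a forward stepwise-mutation-model cohort simulator so every stage can be
    exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    igraph,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan
Config/testthat/edition: 3
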