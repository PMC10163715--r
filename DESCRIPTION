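Package: hybridASE
Title: Allele-Specific Expression and Expression-Based Linkage Mapping in
    Cave x Surface Hybrids
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for hybrid-transcriptomics inference between two diverged
    populations (a cave and a surface ecomorph of the same species) without a
    reference genome. The package pairs the two population transcriptomes by
    reciprocal best hits, builds a combined two-allele reference, assigns
    sequencing fragments to alleles via diagnostic sites, screens F1 hybrids
    for allele-specific expression with a ratio threshold intersected with
    dual-reference concordant differential expression, confirms candidates by
    exact binomial tests on fixed diagnostic-SNP allele counts against both
    references, and places genes on a genetic map by scanning F2 individuals
    for expression-derived genotypes that cosegregate with recessive
    phenotypes, using an exhaustive permutation null and Mendelian pattern
    probabilities. A synthetic-data generator reproduces the full study
    design (paired transcriptomes with fixed SNPs, parental / F1 / F2
    cohorts, planted expression and linkage signals) so every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Genetics, SNP
RoxygenNote: 7.3.3
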