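Package: haplopop
Title: Population Structure Inference from Sparse Pseudo-Haploid SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Population-genomic analysis of sparse, pseudo-haploid SNP
    genotypes of the kind produced by reduced-representation sequencing
    (SLAF-seq, RAD-seq) or low-coverage ancient-DNA workflows, where one
    allele is sampled at random per site and per-site missingness is high.
    Provides pairwise-mismatch-rate (PMR) screening for duplicate and
    related individuals, missing-data-aware principal component analysis
    via a pairwise-complete similarity matrix, a haploid adaptation of the
    Weir-Cockerham F_ST estimator with label-permutation empirical
    p-values, outgroup f3 and f4 statistics with weighted genomic
    block-jackknife standard errors, EIGENSTRAT and VCF input/output, and
    a Balding-Nichols synthetic-data generator with planted duplicates and
    migrant outliers for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
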