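Package: genarch
Title: Twin, SNP-Based, and Genome-Wide Association Analysis of a
    Longitudinal Quantitative Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three complementary estimates of genetic influence on a
    quantitative behavioral trait measured at several ages: classical
    twin variance-component models (ACE/ADE and nested submodels fitted
    by full-information maximum likelihood), SNP heritability from
    unrelated individuals via a genomic relatedness matrix and
    restricted maximum likelihood (GCTA-style GREML), and a genome-wide
    association scan using a one-degree-of-freedom score test of an
    equal SNP effect across measurement ages with genomic control.
    Includes genotype and sample quality control (Hardy-Weinberg,
    minor-allele frequency, missingness, plate effects, relatedness
    pruning, LD pruning, PCA with Tracy-Widom component selection),
    rank-based inverse-normal transformation and covariate
    residualization, noncentral chi-square QTL power analysis, and a
    synthetic-data generator producing twin, genotype and longitudinal
    phenotype panels with known architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
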