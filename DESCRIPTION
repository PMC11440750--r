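Package: metagblup
Title: Single-Step Genomic Evaluation with Metafounders and Unknown Parent
    Groups, Validated by the LR Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for combined genomic evaluation of closely
    related livestock populations. Simulates multi-line, partially crossed,
    partially unrecorded pedigreed populations with SNP genotypes and
    maternally influenced traits; characterises population structure
    (pairwise Wright's Fst, genotype PCA, PCA-based breed assignment);
    defines metafounders or unknown parent groups by population and 5-year
    birth cohort and estimates their ancestral relationship matrix Gamma by
    generalized least squares or by a linear inbreeding-trend construction;
    builds pedigree (A, A-Gamma), genomic (VanRaden G, blended G05) and
    single-step H-inverse relationship matrices under both grouping models;
    assembles and solves multitrait Henderson mixed-model equations with
    maternal, maternal permanent environmental and sire-by-flock-year
    effects; and validates (G)EBVs across reference-population scenarios
    with the LR method (bias, dispersion, accuracy ratio and accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    knitr
Config/testthat/edition: 3
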