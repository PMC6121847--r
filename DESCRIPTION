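Package: OpsinShift
Title: Convergent Visual-System Evolution from Cone Opsin Expression Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing convergent evolution of colour vision in
    fishes from bulk retinal RNA-seq count tables. Computes proportional
    cone opsin expression and an expression-weighted predicted spectral
    sensitivity index, normalises cyp27c1 expression (per-million and
    species-relative), runs rank-based statistics (Scheirer-Ray-Hare
    two-factor tests, per-species Kruskal-Wallis tests with
    Benjamini-Hochberg correction, exact Spearman rank-maintenance tests),
    and tests for phenotypic parallelism of population-level change in
    (sensitivity, cyp27c1) space with a vector-angle/length permutation
    test. Includes consensus calling of opsin coding sequences from
    site-level pileups with IUPAC heterozygote codes, detection of
    amino-acid sites variable within species, and a Dirichlet-multinomial
    simulator that generates datasets with the compositional structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Visualization
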