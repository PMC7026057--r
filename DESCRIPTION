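Package: CqStability
Title: Reference-Gene Stability Validation and RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation of candidate reference genes for RT-qPCR and
    normalization of genes of interest. Implements the four standard
    stability algorithms (geNorm, NormFinder, BestKeeper and the
    comparative delta-Ct method) on efficiency-corrected quantitation
    cycles, aggregates their rankings into a RefFinder-style consensus by
    geometric mean of ranks, determines the optimal number of reference
    genes from the pairwise variation of sequential normalization
    factors, quantifies relative fold changes against a calibrator group
    with ANOVA/Tukey/Dunnett significance testing, and evaluates stepwise
    reduction of the reference-gene set. Includes a seeded generator of
    synthetic Cq datasets with known ground-truth stability structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
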