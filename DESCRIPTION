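Package: nestbarcode
Title: Plant DNA Metabarcoding of Mixed-Origin Woody Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-marker (rbcL/trnL) plant DNA
    metabarcoding of mixed-origin woody material such as paper-wasp nests
    and artificial bark mixtures. Implements top-bit-score consensus
    taxonomy assignment from BLAST tabular hit tables with checklist
    demotion, negative-control and proportion-threshold filtering with
    renormalization, a two-marker median-proportion consensus, mock-community
    evaluation (false-positive/false-negative accounting and linear
    mixed-effects calibration of observed against true proportions), and
    community statistics for nest composition: Shannon (log2) and Chao1
    diversity, exact and normal-approximation Mann-Whitney tests, Spearman
    correlation matrices, correspondence analysis, Euclidean-distance
    dendrograms with Newick export, analytic sample-based rarefaction,
    bipartite wasp-plant summaries and landscape regressions. A seeded
    simulator generates mock-community and nest-study data with marker
    bias and contamination for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
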