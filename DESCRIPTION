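Package: allodater
Title: Dating Whole-Genome Duplication and Allopolyploid Hybridization
    from Ks and Transposable-Element Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the polyploid history of plant
    genomes from collinear gene pairs and transposable-element (TE)
    divergence landscapes. Implements Nei-Gojobori (NG86) counting of
    synonymous and nonsynonymous substitutions with Jukes-Cantor
    correction, tandem-duplicate filtering, Gaussian mixture modelling of
    Ks distributions with BIC model selection, Kimura 2-parameter TE
    divergence profiles with kernel-density intersection finding, and the
    internally calibrated dating equations that convert Ks peaks and TE
    crossing points into absolute times for whole-genome duplication and
    genome-merger (hybridization) events. Also provides karyotype event
    arithmetic, windowed progenitor gene-retention tracks along
    allopolyploid chromosomes, and a multistep selector of
    lineage-discriminating orthogroups combining z-score outlier
    screening, phylogenetic-signal filtering (Blomberg's K, Pagel's
    lambda), Welch's t screening, and recursive feature elimination under
    three classifiers. A synthetic-data generator with known truth makes
    every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    glmnet,
    graphics,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    mclust,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
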