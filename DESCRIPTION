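Package: occubiome
Title: Occupation Inference from Oral and Gut Metagenomic Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compositional analysis pipeline for distinguishing occupational
    groups (for example students versus manual laborers) from annotated
    metagenomic feature-count tables of saliva or fecal samples. Implements
    relative-abundance preprocessing with removal of undetermined features,
    Shannon alpha diversity with normality- and variance-driven test
    selection, Hellinger-distance beta diversity with principal coordinates
    analysis and ANOSIM permutation tests, per-feature differential abundance
    with Bonferroni correction, a two-class LDA effect-size (LEfSe-style)
    screen, Bayesian-multiplicative zero replacement, and a recursive
    feature-elimination random-forest classifier with best-model selection.
    Ships a Dirichlet-multinomial synthetic study generator so the whole
    pipeline is testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
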