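Package: pcmscreen
Title: Proteochemometric Random-Forest Virtual Screening for Transporter Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A proteochemometric (PCM) modelling pipeline for discovering
    transporter inhibitors by virtual screening. Curates and merges public
    pChEMBL-valued bioactivity data with single-concentration percent-of-control
    screening data, selects dual activity thresholds by grid search against a
    QSAR benchmark, builds functional-class circular fingerprint and
    physicochemical ligand descriptors together with z-scale protein
    descriptors from a multiple sequence alignment, trains random-forest
    PCM classifiers under several cross-validation designs, and applies a
    prospective selection procedure (probability pre-filter, diversity
    medoids, and analog picks) to a screening library. Ships a synthetic-data
    generator with planted structure-activity ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    ranger,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
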