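Package: aceqsar
Title: QSAR Modeling of ACE-Inhibitory Dipeptides with a Back-Propagation
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modeling of
    angiotensin-converting enzyme (ACE) inhibitory dipeptides. Peptides are
    encoded with the three Z-scale amino-acid descriptors (hydrophilicity,
    size/shape, electronic properties), min-max normalized, and regressed on
    log(1/IC50) activity with a three-layer feed-forward network trained by
    full-batch gradient descent with momentum (tansig hidden layer, linear
    output). Includes the packaged 58-dipeptide activity dataset, a
    hidden-layer-size model-selection sweep, a back-stepping
    connection-weight importance analysis, protein amino-acid composition
    and protease C-terminal specificity screening for in-silico selection of
    hydrolysis enzymes, pH-stat degree-of-hydrolysis and ACE-inhibition
    assay calculators, and a synthetic dipeptide-dataset generator for
    end-to-end validation of training and importance recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    nnet,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
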