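Package: branchflow
Title: Asymmetric Branching Morphometrics and Classification for Neuronal
    and Glial Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphometric analysis of neuronal and glial branching from
    SWC reconstructions. Converts sample-level reconstructions to
    branch-level trees, computes asymmetric daughter/parent radius scale
    factors (mean and difference), leaf numbers and relative leaf numbers,
    evaluates the power-loss recursion for hierarchically branching
    resistive networks, and benchmarks seven classifiers on two- versus
    three-dimensional feature spaces with DeLong AUC confidence intervals
    and image-level accuracy. Includes a deterministic synthetic-arbor
    generator with level-dependent branching statistics and a pixel-size
    quantization model of the resolution artifact filtered at beta >=
    0.999.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pROC,
    e1071,
    randomForest,
    rpart,
    class,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'swc-io.R'
    'branch-graph.R'
    'scale-features.R'
    'theory.R'
    'synthetic-data.R'
    'classify-eval.R'
    'branchflow-package.R'
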