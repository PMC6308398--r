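Package: physioaffect
Title: User-Customized Negative-Emotion Classification from Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying negative versus basic (neutral) emotional
    state from peripheral physiological recordings (electrocardiogram, skin
    temperature, and electrodermal activity). The package extracts sixteen
    windowed autonomic features (nine heart-rate-variability, two skin
    temperature, five electrodermal), removes outlying windows by per-class
    Mahalanobis distance, ranks features by Kullback-Leibler divergence
    between class-conditional distributions with an information-gain
    convergence stopping rule, and evaluates a one-hidden-layer perceptron
    (with linear and quadratic discriminant comparators) under leave-one-out
    cross-validation. A seedable synthetic-recording simulator with
    condition-dependent autonomic effects makes every stage testable without
    human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'physioaffect-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'outliers.R'
    'utils.R'
    'classify.R'
    'preprocess.R'
    'wavelet.R'
    'features.R'
    'featselect.R'
    'io.R'
    'synthdata.R'
    'pipeline.R'
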