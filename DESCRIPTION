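Package: curricnet
Title: Curriculum and Continual-Learning Experiments with Small Convolutional Networks on Composed Digit Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds digit-scene task sets whose error signal is orthogonal (or not)
    to the component digit classes, trains a small two- or three-layer convolutional
    network under static and continual (exemplar-incremental) curricula, and evaluates
    four families of automated task-switching metrics (performance thresholds, initial
    competence, prediction gain, and the empirical Fisher Information of the weights)
    against a top-decile optimal-switching-window criterion. Includes a synthetic
    glyph-corpus generator with per-writer style variation, an IDX container
    reader/writer so real handwritten-digit data can be substituted, scaled-down
    scenario fixtures for every studied phenomenon, and reporting utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    ggplot2,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
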