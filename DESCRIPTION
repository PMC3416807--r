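Package: alemaps
Title: Coordinate-Based Meta-Analysis of Neuroimaging Activation Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Activation likelihood estimation (ALE) for coordinate-based
    meta-analysis of neuroimaging experiments: Gaussian modeling of reported
    activation peaks, permutation null distributions with false discovery rate
    thresholding and cluster-extent filtering, multi-network probabilistic
    overlap and conjunction maps, meta-analytic connectivity modeling (MACM),
    representational similarity analysis of task networks (1-r distances,
    spectral matrix reordering, Ward dendrograms, classical multidimensional
    scaling), and literature term statistics (Jaccard co-occurrence,
    forward and reverse Bayesian inference). Includes a synthetic-data
    generator that plants known network structure so every pipeline stage can
    be validated against ground truth, plus a one-command study pipeline with
    full provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
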