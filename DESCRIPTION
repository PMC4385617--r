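Package: kernlink
Title: Supervised Network Link Prediction with Pairwise Kernels and
    Multiple Kernel Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised inference of interaction-network links from
    heterogeneous node-level kernel data. Implements five pairwise kernels
    (tensor product, direct sum, metric learning, cosine and Cartesian
    product forms) built on top of node kernels, simplex-constrained
    multiple kernel learning with a support vector machine dual solver,
    sigmoid calibration of decision values into link probabilities,
    cautious classification with a reject option, and sequential
    data-cleaning strategies that down-weight mislabelled training pairs.
    Ships a planted-partition synthetic benchmark generator so every
    component can be exercised without external data, and a small
    command-line interface over the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
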