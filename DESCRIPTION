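Package: slidesieve
Title: Evolutionary Feature Selection to Remove Acquisition-Site Bias from
    Histopathology Image Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep features extracted from whole-slide histopathology images
    carry signatures of the hospital that scanned the slide, so classifiers
    and image-search engines can exploit acquisition-site shortcuts instead
    of tissue morphology. slidesieve selects compact feature subsets with a
    binary-encoded NSGA-III genetic algorithm driven by three objectives:
    maximise diagnosis-level image-search quality (macro F1 of k-nearest
    neighbour retrieval), minimise the accuracy of a linear support vector
    machine trained to recognise the source institution (the bias
    indicator), and minimise the number of retained features. The package
    ships the full experimental pipeline (per-tumour-type runs, replicate
    management, Pareto-front solution picking, held-out and external
    validation, Wilcoxon significance testing) together with a synthetic
    benchmark generator that plants class-informative, site-biased,
    confounded and noise dimensions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
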