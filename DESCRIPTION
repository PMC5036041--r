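Package: colonymorph
Title: Quantitative Morphology Profiling and Quality Control for
    Pluripotent Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free quantitative evaluation of human pluripotent
    stem-cell colony morphology from phase-contrast well images. Provides a
    seedable synthetic phase-contrast image generator with ground-truth
    masks, a six-step colony recognition pipeline (background flattening,
    texture-trained pixel classification, noise reduction, object filling,
    manual cleansing hooks and size gating), a 120-parameter morphometric
    panel organised into frequency, shape and volume families with
    correlation and coefficient-of-variation parameter selection,
    average-linkage hierarchical clustering under uncentred correlation
    with no-correlation-test dendrogram pruning, nearest-correlation
    classification of live colonies against a clustered colony database,
    and a statistical tail for validating morphology clusters against
    single-colony expression profiles (percentile-shift normalisation,
    cluster-versus-rest testing with Benjamini-Hochberg control,
    fold-change screens, expression clustering and PCA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
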