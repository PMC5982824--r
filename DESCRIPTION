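Package: sweepimage
Title: Classify Selective Sweeps from Unphased Genotypes with
    Summary-Statistic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies recent selective sweeps from unphased
    diploid genotype data. A genomic region is split into 11 subwindows, 12
    unphased summary statistics (nucleotide diversity, Watterson's theta,
    Tajima's D, moments of the pairwise genotype-distance distribution,
    multilocus-genotype frequency spectrum statistics J1/J12/J2-J1, and
    genotypic-LD based ZnS and omega-max) are computed per subwindow and
    spatially normalized into a 12 x 11 feature image. A multi-branch
    convolutional neural network (with an Extra-Trees baseline) trained on
    forward-simulated sweeps assigns each region to one of five classes:
    hard sweep, soft sweep, linked-hard, linked-soft, or neutral. Includes a
    self-contained rescaled Wright-Fisher simulator for generating labeled
    training data, ms-style and VCF input, and plotting and tidying helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
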