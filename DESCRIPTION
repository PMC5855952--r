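Package: shapesorter
Title: Allele-Specific SHAPE-MaP Analysis and RiboSNitch Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific analysis of SHAPE mutational-profiling
    (SHAPE-MaP) experiments. Simulates MaP sequencing reads from ground-truth
    reactivity profiles with two-allele mixtures, sorts aligned reads by the
    base observed at a variant site, computes background-corrected and
    normalized per-allele SHAPE reactivity profiles, compares allele profiles
    to call riboSNitches (variants that change RNA secondary structure), and
    evaluates the within-sample ratiometric design against the traditional
    between-replicate design with ROC/AUC. Also provides sliding-window
    structure analytics (median reactivity, multi-scale correlation,
    similar/dissimilar region calls, bootstrap enrichment against annotation
    tracks) and k-medoids clustering of dot-bracket structure ensembles with
    medoid extraction and cluster-population shift statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
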