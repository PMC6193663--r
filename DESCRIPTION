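Package: osgminer
Title: Structured Patient Journeys from Online Support Group Discussions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms unstructured online support group (OSG) discussions
    about prostate cancer into structured per-patient journeys: collocated
    chronological post streams, self-disclosed demographics and clinical
    markers (Gleason score, PSA), treatment decision-making behaviour
    (Paternalistic, Autonomous, Shared) classified from sentence-level
    template patterns, decision factors, treatment-anchored side-effect
    timelines over relative months, and 16-dimensional lexicon-based
    emotion trajectories with intensity-modifier and negation handling.
    Includes a skip-gram word-embedding trainer for nearest-neighbour
    lexicon expansion, group-level aggregate reporting with chi-squared
    and t-test comparisons, and a seeded synthetic-corpus generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
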