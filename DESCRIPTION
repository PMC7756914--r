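Package: symdyn
Title: Dynamic Time Warping Analysis of Depression Symptom Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse the temporal dynamics of depression symptoms measured
    repeatedly with the 17-item Hamilton Rating Scale for Depression
    (HRSD-17). Pairwise dynamic time warping (DTW) distances between item
    trajectories are computed per patient (idiographic analysis) and
    aggregated across a cohort (nomothetic analysis), feeding Ward.D2
    hierarchical clustering, symptom networks with strength and closeness
    centrality, a Distatis three-way multidimensional-scaling compromise,
    per-item mixed-effect trajectory models, and a comparison of network
    density between treatment responders/remitters and other patients.
    A seeded generator of HRSD-17-like longitudinal cohorts with known
    latent cluster structure supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils,
    tidyr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
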