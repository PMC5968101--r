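Package: irritmap
Title: Irritative-Zone Mapping from Scalp EEG with Paired Histology Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the cortical generators of interictal epileptiform
    discharges (IEDs) recorded with a multichannel scalp EEG mini-cap, and runs
    the paired target-versus-control histology statistics used to characterize
    the identified irritative zones. Provides analytic multi-shell sphere and
    boundary-element (BEM) forward head models, robust threshold-based IED
    detection with spike (20-70 ms) and sharp-wave (70-200 ms) duration bands,
    constrained three-way PARAFAC tensor decomposition with k-means subtype
    clustering, sLORETA standardized minimum-norm source imaging at the
    two-thirds-of-peak latency, target/contralateral-control region selection,
    shrinkage-corrected brain-sectioning coordinates, and stained-area /
    object-count image quantification with normality-gated paired tests. A
    synthetic-data module simulates recordings with known IED subtypes and
    paired histology tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    pracma,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
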