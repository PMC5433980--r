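Package: mycoverlap
Title: Fungal-Host Diversity and Overlap in Mycoheterotrophic Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how mycoheterotrophic plants share and
    diversify their arbuscular-mycorrhizal fungal hosts. Computes Faith
    phylogenetic diversity (PD) of fungal host sets with exact minimum- and
    maximum-PD subset algorithms for equal-size normalisation, pairwise and
    group host-overlap indices (Bray-Curtis, min-overlap), exhaustive
    same-size group ensembles with min-max scaling, permutation Mantel
    tests, Pearson and partial Pearson correlations, and Welch two-sample
    comparisons between same-location and mixed-location groups. Includes
    a synthetic-data generator emulating the statistical structure of
    location-structured plant-fungus incidence surveys, so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
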