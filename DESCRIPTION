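Package: trabecula
Title: Whole-Bone Trabecular Morphometry and Ontogenetic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Holistic (whole-bone) trabecular bone morphometry from microCT
    voxel volumes, and the nonparametric statistics used to study its change
    across an ontogenetic series. Segments cortical from trabecular bone,
    cuts a metacarpal-like volume into anatomical regions, quantifies bone
    volume fraction and mean-intercept-length anisotropy on a background grid
    of overlapping spherical volumes of interest, computes sphere-fitting
    trabecular thickness, separation and number, interpolates grid samples
    onto a tetrahedral mesh of the inner trabecular region, and runs
    age-category Kruskal-Wallis/Nemenyi tests, inter-region ratios and
    principal component analyses. A synthetic-data module generates phantoms
    with analytic ground truth and whole synthetic metacarpals with an
    ontogenetic cohort structure so that every stage is testable without
    museum scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
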