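Package: wingmorph
Title: Geometric Morphometrics of Paired Insect Wings with Asymmetry and
    Admixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for bilaterally paired
    structures such as honeybee forewings.  Implements generalized Procrustes
    superimposition with matching symmetry (mirrored left sides), centroid
    size, two-way mixed-model ANOVA and Procrustes ANOVA partitioning
    directional and fluctuating asymmetry from nested measurement-error
    strata, fluctuating-asymmetry scores with ICC(2,1) repeatability,
    two-block partial least squares with Escoufier's RV coefficient and
    permutation tests, between-group PCA with leave-one-out cross-validated
    classification, phenotypic trajectory (vector-angle) analysis, and
    hybrid-index based group comparisons.  Ships a calibrated synthetic-data
    generator producing admixed wing + microsatellite datasets with known
    ground truth, readers and writers for TPS and long-format CSV landmark
    files, and a single-call analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
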