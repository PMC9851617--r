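Package: somatomap
Title: Surface-Based Somatotopic Mapping and Remapping Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying somatotopic organisation and
    deprivation-triggered remapping on triangulated cortical surface
    patches. Implements winner-takes-all body-part mapping from
    block-design GLM estimates, cluster-weighted centres of gravity with
    signed geodesic distances to a hand-border anchor, surface-coverage
    laterality indices, Jaccard map-overlap analysis with leave-self-out
    group averaging, and cross-validated Mahalanobis (crossnobis)
    representational similarity analysis with multivariate noise
    normalisation.  A deterministic synthetic-cohort generator (flat
    cortical patch, three groups, two hemispheres, block protocol)
    makes every stage testable without imaging data, and questionnaire
    scoring utilities compute chronic phantom-limb pain and sensation
    scores from frequency-coded ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
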