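Package: atcprofiles
Title: Medication-Profile Clustering and Longitudinal Cluster Tracing for
    Type 2 Diabetes Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds patient medication profiles over the Anatomical
    Therapeutic Chemical (ATC) drug-classification hierarchy from free-text
    electronic medical records, applies a reproducible inclusion/exclusion
    cascade for type 2 diabetes cohorts, clusters profiles within 10-year
    age groups by agglomerative hierarchical clustering cut at a fixed
    merge-height threshold, traces cluster identities across adjacent age
    groups by centroid distance, and summarises patient flows between
    clusters as Not-Worse/Worse transition odds. Includes a seedable
    synthetic electronic-medical-record generator with planted medication
    archetypes so the entire pipeline is testable without access to
    restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
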