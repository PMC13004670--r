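Package: humoralkit
Title: Humoral Immunity Analysis for Checkpoint-Blockade Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the B-cell and plasma-cell arm of the antitumor
    immune response from single-cell, spatial and serological assays.
    Provides BCR clonotype construction and expansion calling from AIRR
    rearrangement tables, immunoglobulin isotype assignment with
    gene-expression rescue, Dirichlet-regression differential abundance
    of cell-state compositions with likelihood-ratio testing, detection
    of tertiary-lymphoid-structure-like communities and plasma-cell
    infiltration scores from multiplex-IHC centroid tables, ELISA
    endpoint-titer interpolation, ELISpot positivity calls and
    protein-microarray autoantibody hit counting. A seeded synthetic
    cohort generator emulates the statistical structure of all inputs so
    the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
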