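Package: alloTCR
Title: Donor-Reactive T-Cell Clone Identification and Longitudinal
    Tracking from TCRbeta Repertoires
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies donor-reactive T-cell clones (DRTC) from paired
    mixed-lymphocyte-reaction (MLR) sorted versus unstimulated TCRbeta
    clonotype repertoires using an exact two-sided binomial test under a
    repertoire-size-weighted null with Benjamini-Hochberg false discovery
    control and fold-change gating, and tracks those clones across blood,
    allograft biopsy and urine samples over time. Provides clonotype-table
    readers for immunoSEQ-export and AIRR-style columns, repertoire overlap
    indices (Morisita-Horn, Jaccard), DRTC breadth and depth metrics,
    compartment categorization of graft-infiltrating clones, urine-to-biopsy
    overlap reports, nonparametric group comparisons, and a synthetic
    transplant-cohort generator with recorded ground truth so the whole
    pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Transcriptomics, Sequencing, ImmunoOncology
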