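Package: qusrim
Title: Quantitative Ultrasound Characterization of Tumours and Peritumoral Tissue
Version: 0.1.0
Authors@R:
    person("QUS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ultrasound (QUS) tissue characterization
    of breast lesions from raw radiofrequency (RF) echo data. Implements
    envelope detection and log compression, Nakagami shape-parameter and
    weighted-entropy estimation, directional gray-level co-occurrence matrix
    (GLCM) texture features, sliding-window parametric maps with
    reference-phantom depth correction, internal-tumour and peritumoral-rim
    region-of-interest construction, and lesion classification by k-nearest
    neighbours with leave-one-out cross-validation, ROC analysis and
    exhaustive feature-subset search. A synthetic-cohort generator with
    controlled speckle statistics makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
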