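Package: morbclust
Title: Fuzzy C-Means Clustering of Medical Specialty Co-Involvement in
    Multimorbidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Groups hospital patients with multimorbidity by the set of
    medical specialties simultaneously involved in their care. Implements
    fuzzy c-means clustering of a patient-by-specialty binary involvement
    matrix with multistart cost minimization, validity-index-driven
    selection of the fuzziness parameter and cluster count (Xie-Beni,
    partition coefficient, partition entropy, silhouette), cluster
    labeling through observed/expected and exclusivity ratios, and a
    membership-banding algorithm that enumerates full-membership,
    dominant, and combination subgroups of patients. Ships a synthetic
    encounter-record generator with planted overlapping involvement
    structure so the whole pipeline can be exercised and validated
    without access to restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust
Suggests:
    cluster,
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
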