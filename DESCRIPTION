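Package: fcranker
Title: Rescoring Peptide-Spectrum Matches by Fuzzy Classification and
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-database-search rescoring of peptide-spectrum matches
    (PSMs) from shotgun proteomics. Each target PSM receives a confidence
    score produced by iterating an instance-weighted linear-programming
    support vector machine against a fuzzy silhouette cluster-validity
    index, so that correct target PSMs are separated from incorrect
    targets and decoys without relying on the unreliable target labels.
    Includes target-decoy false discovery rate accounting, ROC utilities,
    a synthetic PSM generator for validation, reduced-column and
    subsampled-silhouette modes for large collections, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
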