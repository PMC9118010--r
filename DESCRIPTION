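Package: morbclust
Title: Multimorbidity Networks and Graph Clustering of Diagnosis Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease co-occurrence networks from patient visit records
    coded in ICD-10, using relative risk between diagnosis blocks as edge
    strength, and partitions the network into multimorbidity clusters with a
    k-means-style graph clustering algorithm (the K-algorithm refined by a
    merge/split M-algorithm) minimizing the inverse-internal-weight cost.
    Includes record filtering at ICD-10 block precision, sigmoid edge-weight
    normalization, silhouette-based selection of the number of clusters,
    cluster-level demographic and cost summaries, a synthetic cohort generator
    with planted disease groups for validation, and an exhaustive-enumeration
    oracle for small graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
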