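Package: ligfish
Title: Ligand-Based Target Fishing by Similarity Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein targets for small molecules by ranking a
    reference library of targets, each represented solely by its set of
    experimentally active ligands. A query molecule is scored against every
    target by data fusion of circular-fingerprint Tanimoto similarities
    (Max, k-nearest-neighbour and Centroid schemes) and targets are returned
    as a descending-score interaction profile. Includes curation tools that
    turn raw bioactivity tables into a deduplicated reference library,
    ranked-retrieval evaluation metrics (precision, recall, F score and
    uninterpolated average precision at rank m), cross-validation and
    subsampling experiment runners, and a synthetic benchmark generator with
    controlled within- and between-target similarity so the whole pipeline
    is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    jsonlite,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
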