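Package: drimm
Title: Driver Missense Mutation Classification with Rotation Forests and
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies missense mutations as cancer drivers or neutral
    passengers from protein sequence and annotation. Encodes each mutation
    in four feature families (physicochemical residue-change differences,
    substitution-matrix scores, dipeptide 2-gram sequence profiles in the
    20-letter and reduced 6-letter alphabets, and annotated attributes),
    ranks features by a Fisher-style discriminant score (DX) or by
    minimum-redundancy maximum-relevance mutual information (mRMR), picks
    the optimal feature prefix by incremental feature selection under
    repeated stratified cross-validation, and trains a rotation-forest
    ensemble on the selected features. Ships a synthetic mutation-dataset
    generator with planted class structure so the full pipeline can be
    exercised and benchmarked without external databases, plus a
    command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    rpart,
    seqinr,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
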