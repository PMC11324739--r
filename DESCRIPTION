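Package: acdx
Title: Adhesive Capsulitis Diagnosis from Radiomic Features via Model Checking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the automatic diagnosis of adhesive capsulitis
    ("frozen shoulder") from slice-wise radiomic feature tables of shoulder
    MRI exams. Native first-order and gray-level co-occurrence matrix (GLCM)
    texture features are computed from image arrays; per-feature values are
    discretized to low/medium/high levels by cohort-pooled tertiles; each
    patient exam is compiled into a small process-algebra (CCS) model whose
    slices are processes interleaving the slice's feature actions; disease
    signatures expressed as level patterns compile to temporal-logic formulas
    checked by a fixpoint model checker over the finite labeled transition
    system, yielding a binary diagnosis per patient which is combined across
    coronal and sagittal planes with a logical OR. Includes cohort evaluation
    (confusion matrices, accuracy/precision/recall/specificity, and exact
    integer confusion-matrix recovery from printed metric triples) and a
    seedable synthetic-cohort generator that plants signatures to a requested
    confusion matrix, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
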