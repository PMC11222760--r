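Package: litddx
Title: Literature-Guided Differential Diagnosis from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A retrieval-based diagnostic decision support pipeline that maps
    a free-text patient note to a ranked differential diagnosis. A clinical
    note is filtered down to its recognizable medical terms with a
    dictionary-based concept matcher, the filtered query retrieves the
    top-scoring literature abstracts from a BM25 inverted index, concept
    frequencies are aggregated over the retrieved set, and candidate
    diagnoses are ranked by a concept-level TF-IDF score. The ranking can be
    fused with a second (supervised) ranker via reciprocal rank fusion with a
    training-count fallback rule. Includes mean-reciprocal-rank and
    mean-average-precision evaluation stratified by training-note frequency,
    a synthetic long-tailed benchmark generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
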