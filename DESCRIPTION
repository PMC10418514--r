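Package: trialmatchr
Title: Patient-to-Trial Matching with Pluggable Language-Model Backends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for matching free-text patient notes to
    clinical-trial records: keyword-based hybrid retrieval with decaying
    reciprocal-rank fusion, criterion-level eligibility classification
    through a pluggable language-model backend, and trial-level score
    aggregation and ranking.  Includes TREC-style readers and writers for
    runs and relevance judgments, graded information-retrieval metrics
    (NDCG@k, normalized P@k, Recall@k, AUROC), natural-language-inference
    baseline scoring, a synthetic-cohort generator with planted ground
    truth, and a deterministic oracle backend so the full pipeline can be
    exercised and tested without network access or model weights.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
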