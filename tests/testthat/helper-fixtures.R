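# Shared fixture builders: everything is generated in code at test time.

# Small synthetic cohort for fast end-to-end tests.
tiny_cohort <- function(seed = 7L) {
  generate_cohort(cohort_config(
    n_patients = 4L, n_trials = 30L,
    eligible_per_patient = 3L, excluded_per_patient = 2L,
    potential_per_patient = 1L, irrelevant_per_patient = 1L,
    seed = seed
  ))
}

# Three-trial toy corpus with known token statistics for BM25 arithmetic.
toy_trials <- function() {
  list(
    trial_record("NCT0000001", brief_title = "Insulin therapy in diabetes",
                 conditions = "diabetes", interventions = "insulin",
                 brief_summary = "Insulin dosing in adults with diabetes.",
                 inclusion_criteria = "Diagnosis of diabetes.",
                 exclusion_criteria = "Pregnancy."),
    trial_record("NCT0000002", brief_title = "Statin therapy in hyperlipidemia",
                 conditions = "hyperlipidemia", interventions = "statin",
                 brief_summary = "Statin dosing in adults.",
                 inclusion_criteria = "Diagnosis of hyperlipidemia.",
                 exclusion_criteria = "Liver failure."),
    trial_record("NCT0000003", brief_title = "Diabetes prevention with lifestyle change",
                 conditions = "prediabetes", interventions = "lifestyle",
                 brief_summary = "Lifestyle change for prevention of diabetes.",
                 inclusion_criteria = "Elevated fasting glucose.",
                 exclusion_criteria = "Diabetes diagnosis.")
  )
}

# A trial_match_result with the given label vectors (no backend involved).
fake_match_result <- function(inc_labels, exc_labels,
                              patient_id = "p1", trial_id = "t1") {
  mk <- function(labels, side) {
    lapply(seq_along(labels), function(k) {
      criterion_assessment(k - 1L, "synthetic assessment", integer(0), labels[k], side)
    })
  }
  structure(
    list(
      patient_id = patient_id, trial_id = trial_id,
      inclusion_assessments = mk(inc_labels, "inclusion"),
      exclusion_assessments = mk(exc_labels, "exclusion"),
      backend_metadata = list(backend_id = "fixture", cached = FALSE)
    ),
    class = "trial_match_result"
  )
}

# Independent brute-force evaluator of the decaying reciprocal-rank fusion
# double sum.  `rankings` is a list of entries list(keyword_index, trial_ids)
# (trial_ids in rank order); retrievers are simply separate entries.
brute_force_fusion <- function(rankings, trial_ids, C = 20) {
  scores <- setNames(numeric(length(trial_ids)), trial_ids)
  for (tid in trial_ids) {
    s <- 0
    for (r in rankings) {
      pos <- match(tid, r$trial_ids)
      if (!is.na(pos)) s <- s + 1 / (r$keyword_index * (pos + C))
    }
    scores[tid] <- s
  }
  scores
}

# Independent brute-force metric evaluators.
brute_force_dcg <- function(rel, k) {
  total <- 0
  for (x in seq_len(min(k, length(rel)))) total <- total + rel[x] / log2(x + 1)
  total
}
brute_force_ndcg <- function(rel, ideal, k) {
  idcg <- brute_force_dcg(sort(ideal, decreasing = TRUE), k)
  if (idcg == 0) return(0)
  brute_force_dcg(rel, k) / idcg
}
brute_force_precision <- function(rel, k) sum(rel[seq_len(min(k, length(rel)))]) / (2 * k)
brute_force_recall <- function(rel, R_total, k) sum(rel[seq_len(min(k, length(rel)))]) / R_total
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Backend answering matching requests from a fixed per-criterion template.
scripted_matching_backend <- function(label_for, id = "scripted") {
  make_backend(id, function(request) {
    stopifnot(request$purpose == "matching")
    side <- request$meta$side
    n <- request$meta$n_criteria
    out <- list()
    for (k in seq_len(n)) {
      out[[as.character(k - 1L)]] <- list(
        explanation = "scripted", sentences = list(),
        label = label_for(side, k)
      )
    }
    as.character(jsonlite::toJSON(out, auto_unbox = TRUE))
  })
}
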