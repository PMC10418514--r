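# Trial-level score aggregation and ranking.
#
# Linear aggregation turns the criterion labels of one patient-trial pair
# into six percentage features.  With M inclusion labels and N exclusion
# labels, and M' = M - #(not applicable), N' = N - #(not applicable):
#
#   pct_met_inclusion    = #(included)               / M'
#   pct_unmet_inclusion  = #(not included)           / M'
#   pct_noinfo_inclusion = #(not enough information) / M'
#   pct_met_exclusion    = #(excluded)               / N'
#   pct_unmet_exclusion  = #(not excluded)           / N'
#   pct_noinfo_exclusion = #(not enough information) / N'
#
# A zero denominator (all labels "not applicable", or an empty side) makes
# all three percentages of that side 0, so fully-not-applicable sides
# neither reward nor penalize.
#
# The backend-aggregated scores are a general relevance R in [0, 100] and
# an eligibility S with |S| <= R.  The combination score is
#
#   combination = pct_met_inclusion
#               - I(pct_unmet_inclusion > 0) - I(pct_met_exclusion > 0)
#               + R/100 + S/100
#
# with I the 0/1 indicator; the /100 normalization puts all five terms on
# a comparable scale and can be switched off.

.side_percentages <- function(labels, met_label, unmet_label) {
  n_total <- length(labels)
  n_na <- sum(labels == "not applicable")
  denom <- n_total - n_na
  if (denom == 0L) {
    return(list(met = 0, unmet = 0, noinfo = 0, denom = 0L))
  }
  list(
    met = sum(labels == met_label) / denom,
    unmet = sum(labels == unmet_label) / denom,
    noinfo = sum(labels == "not enough information") / denom,
    denom = as.integer(denom)
  )
}

#' Linearly aggregate criterion labels into percentage features
#'
#' @param result A `trial_match_result` from [match_patient_trial()].
#' @return A `linear_scores` list with the six percentages
#'   (`pct_met_inclusion`, `pct_unmet_inclusion`, `pct_noinfo_inclusion`,
#'   `pct_met_exclusion`, `pct_unmet_exclusion`, `pct_noinfo_exclusion`)
#'   and the effective denominators `M_prime`, `N_prime`.
#' @export
linear_aggregate <- function(result) {
  inc_labels <- vapply(result$inclusion_assessments, `[[`, character(1), "label")
  exc_labels <- vapply(result$exclusion_assessments, `[[`, character(1), "label")
  inc <- .side_percentages(inc_labels, "included", "not included")
  exc <- .side_percentages(exc_labels, "excluded", "not excluded")
  structure(
    list(
      pct_met_inclusion = inc$met,
      pct_unmet_inclusion = inc$unmet,
      pct_noinfo_inclusion = inc$noinfo,
      pct_met_exclusion = exc$met,
      pct_unmet_exclusion = exc$unmet,
      pct_noinfo_exclusion = exc$noinfo,
      M_prime = inc$denom,
      N_prime = exc$denom
    ),
    class = "linear_scores"
  )
}

#' Validate and clamp backend-aggregated scores
#'
#' Enforces 0 <= relevance <= 100 and |eligibility| <= relevance.
#' Out-of-range values are clamped to the nearest feasible value with a
#' warning rather than rejected, so pipelines stay total under imperfect
#' backends; every clamp is logged.
#'
#' @param relevance,eligibility Numeric scalars from the backend.
#' @return An `aggregate_scores` list with `relevance_score` and
#'   `eligibility_score`.
#' @export
aggregate_scores <- function(relevance, eligibility) {
  if (!is.numeric(relevance) || !is.numeric(eligibility) ||
      length(relevance) != 1L || length(eligibility) != 1L ||
      is.na(relevance) || is.na(eligibility)) {
    .stopf("relevance and eligibility must be numeric scalars")
  }
  r <- relevance
  if (r < 0 || r > 100) {
    r <- min(max(r, 0), 100)
    warning(sprintf("relevance %.3f outside [0, 100]; clamped to %.3f", relevance, r),
            call. = FALSE)
  }
  s <- eligibility
  if (abs(s) > r) {
    s <- sign(s) * r
    warning(sprintf("|eligibility| %.3f exceeds relevance %.3f; clamped to %.3f",
                    abs(eligibility), r, s), call. = FALSE)
  }
  structure(
    list(relevance_score = r, eligibility_score = s),
    class = "aggregate_scores"
  )
}

.aggregation_prompt <- function(patient, trial, result) {
  fmt_side <- function(assessments, criteria) {
    if (length(assessments) == 0L) return("(none)")
    paste(vapply(assessments, function(a) {
      sprintf("%d. %s -> %s", a$criterion_index, criteria[a$criterion_index + 1L], a$label)
    }, character(1)), collapse = "\n")
  }
  paste0(
    "Given the patient note, the clinical trial, and the criterion-level ",
    "eligibility predictions below, rate the patient-trial pair.\n",
    "Return a JSON object {\"relevance\": r, \"eligibility\": s} where r in ",
    "[0, 100] is the general relevance (0 = irrelevant, 100 = exactly ",
    "relevant) and s is the eligibility score with |s| <= r (negative = ",
    "likely excluded).\n\n",
    "Patient note:\n", patient$raw_text, "\n\n",
    "Trial: ", trial$background$brief_title, "\n\n",
    "Inclusion criterion predictions:\n",
    fmt_side(result$inclusion_assessments, trial$inclusion_criteria), "\n",
    "Exclusion criterion predictions:\n",
    fmt_side(result$exclusion_assessments, trial$exclusion_criteria), "\n"
  )
}

#' Aggregate criterion predictions into trial-level scores via the backend
#'
#' @param patient A [patient_note()].
#' @param trial A [trial_record()].
#' @param result The `trial_match_result` for this pair.
#' @param backend Aggregation backend.
#' @param retries Re-sends after a parse failure.
#' @return An [aggregate_scores()] object (validated/clamped).
#' @export
llm_aggregate <- function(patient, trial, result, backend, retries = 3L) {
  req <- backend_request(
    "aggregation", .aggregation_prompt(patient, trial, result),
    meta = list(patient_id = patient$patient_id, trial_id = trial$trial_id)
  )
  for (attempt in seq_len(retries + 1L)) {
    resp <- complete(backend, req)
    parsed <- tryCatch({
      obj <- jsonlite::fromJSON(resp$raw_text, simplifyVector = TRUE)
      if (is.null(obj$relevance) || is.null(obj$eligibility)) {
        stop("missing relevance or eligibility field")
      }
      aggregate_scores(as.numeric(obj$relevance), as.numeric(obj$eligibility))
    }, error = function(e) e)
    if (!inherits(parsed, "error")) return(parsed)
    last_err <- parsed
  }
  .stopf(
    "aggregation failed for patient %s, trial %s after %d attempts: %s",
    patient$patient_id, trial$trial_id, retries + 1L, conditionMessage(last_err)
  )
}

#' Combine linear and backend-aggregated features into one score
#'
#' @param linear A [linear_aggregate()] result.
#' @param aggregate An [aggregate_scores()] result, or `NULL` for the
#'   linear-only variant (first three terms).
#' @param normalize_llm Divide the backend scores by 100 (default) so all
#'   terms share the percentage scale.
#' @return A single numeric combination score.
#' @export
combine_scores <- function(linear, aggregate = NULL, normalize_llm = TRUE) {
  score <- linear$pct_met_inclusion -
    as.numeric(linear$pct_unmet_inclusion > 0) -
    as.numeric(linear$pct_met_exclusion > 0)
  if (!is.null(aggregate)) {
    div <- if (normalize_llm) 100 else 1
    score <- score + aggregate$relevance_score / div + aggregate$eligibility_score / div
  }
  score
}

#' Score every matched patient-trial pair
#'
#' Runs [linear_aggregate()] on each match, optionally [llm_aggregate()]
#' when a backend is supplied, and [combine_scores()].
#'
#' @param matches List of `trial_match_result` objects.
#' @param patients,trials Lists of notes/records covering the matches
#'   (required when `backend` is supplied).
#' @param backend Aggregation backend, or `NULL` for linear-only scoring.
#' @param normalize_llm Passed to [combine_scores()].
#' @return A data.frame (one row per pair) with the patient and trial IDs,
#'   the six linear percentages, `M_prime`, `N_prime`, `relevance`,
#'   `eligibility` (NA without a backend) and `combination`.
#' @export
score_trials <- function(matches, patients = NULL, trials = NULL, backend = NULL,
                         normalize_llm = TRUE) {
  if (!is.null(backend)) {
    patient_by_id <- stats::setNames(patients, vapply(patients, `[[`, character(1), "patient_id"))
    trial_by_id <- stats::setNames(trials, vapply(trials, `[[`, character(1), "trial_id"))
  }
  rows <- lapply(matches, function(m) {
    lin <- linear_aggregate(m)
    agg <- NULL
    if (!is.null(backend)) {
      agg <- llm_aggregate(patient_by_id[[m$patient_id]], trial_by_id[[m$trial_id]], m, backend)
    }
    data.frame(
      patient_id = m$patient_id,
      trial_id = m$trial_id,
      pct_met_inclusion = lin$pct_met_inclusion,
      pct_unmet_inclusion = lin$pct_unmet_inclusion,
      pct_noinfo_inclusion = lin$pct_noinfo_inclusion,
      pct_met_exclusion = lin$pct_met_exclusion,
      pct_unmet_exclusion = lin$pct_unmet_exclusion,
      pct_noinfo_exclusion = lin$pct_noinfo_exclusion,
      M_prime = lin$M_prime,
      N_prime = lin$N_prime,
      relevance = if (is.null(agg)) NA_real_ else agg$relevance_score,
      eligibility = if (is.null(agg)) NA_real_ else agg$eligibility_score,
      combination = combine_scores(lin, agg, normalize_llm = normalize_llm),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank candidate trials by a chosen score
#'
#' @param scores A data.frame from [score_trials()].
#' @param key Ranking key: `"combination"`, `"relevance"`, `"eligibility"`,
#'   or one of the linear feature columns (e.g. `"pct_met_inclusion"`).
#'   Single-feature keys are oriented so that higher means more eligible.
#' @return A [run_list()]: descending by the key, ties broken by ascending
#'   trial ID, 1-based ranks per patient.
#' @export
rank_trials <- function(scores, key = "combination") {
  allowed <- c(
    "combination", "relevance", "eligibility",
    "pct_met_inclusion", "pct_unmet_inclusion", "pct_noinfo_inclusion",
    "pct_met_exclusion", "pct_unmet_exclusion", "pct_noinfo_exclusion"
  )
  if (!key %in% allowed) .stopf("unknown ranking key: %s", key)
  vals <- scores[[key]]
  if (anyNA(vals)) .stopf("ranking key %s contains NA (was a backend supplied?)", key)
  ord <- order(scores$patient_id, -vals, scores$trial_id)
  sorted <- scores[ord, , drop = FALSE]
  run_list(sorted$patient_id, sorted$trial_id, sorted[[key]])
}
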