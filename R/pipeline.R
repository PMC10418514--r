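# End-to-end orchestration: retrieval -> matching -> ranking.

#' Run the full matching pipeline
#'
#' For each patient: generate keywords and retrieve fused candidates,
#' assess every candidate criterion by criterion, aggregate the criterion
#' labels (linear features plus backend aggregation), and rank by the
#' chosen key.
#'
#' @param patients List of [patient_note()] objects.
#' @param trials List of [trial_record()] objects.
#' @param backend Backend used for all three stages (wrap with
#'   [cached_backend()] for reproducible warm runs).
#' @param top_k Retrieval candidates kept per patient.
#' @param match_top Candidates per patient passed to matching (`Inf` for
#'   all retrieved).
#' @param key Ranking key, see [rank_trials()].
#' @param use_llm_aggregation Call the backend for trial-level
#'   relevance/eligibility scores (default) or rank on linear features
#'   only.
#' @param C,max_keywords,depth Retrieval parameters.
#' @return A list with `retrieval_run`, `matches`, `scores` and `run` (the
#'   final ranked [run_list()]).
#' @export
run_pipeline <- function(patients, trials, backend, top_k = 500L,
                         match_top = Inf, key = "combination",
                         use_llm_aggregation = TRUE,
                         C = 20, max_keywords = 32L, depth = 1000L) {
  index <- build_trial_index(trials)
  retrieval <- lapply(patients, function(p) {
    retrieve_candidates(p, index, backend, top_k = top_k, C = C,
                        max_keywords = max_keywords, depth = depth)
  })
  retrieval_run <- do.call(rbind, retrieval)
  class(retrieval_run) <- c("run_list", "data.frame")
  to_match <- retrieval_run[retrieval_run$rank <= match_top, , drop = FALSE]
  matches <- match_all(patients, trials, to_match, backend)
  scores <- score_trials(
    matches, patients, trials,
    backend = if (use_llm_aggregation) backend else NULL
  )
  run <- rank_trials(scores, key = key)
  list(retrieval_run = retrieval_run, matches = matches, scores = scores, run = run)
}
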