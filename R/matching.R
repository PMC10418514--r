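# Criterion-level eligibility matching.
#
# For each patient-trial pair the backend is called at most twice: once
# with all inclusion criteria and once with all exclusion criteria (a side
# with zero criteria is skipped).  Per criterion the backend must return an
# explanation, the IDs of the patient sentences it relied on, and an
# eligibility label from the side-specific closed set:
#   inclusion: included / not included / not enough information / not applicable
#   exclusion: excluded / not excluded / not enough information / not applicable

.INCLUSION_LABELS <- c("included", "not included", "not enough information", "not applicable")
.EXCLUSION_LABELS <- c("excluded", "not excluded", "not enough information", "not applicable")

#' Side-specific eligibility label sets
#' @param side `"inclusion"` or `"exclusion"`.
#' @return Character vector of the four admissible labels for that side.
#' @export
eligibility_labels <- function(side = c("inclusion", "exclusion")) {
  side <- match.arg(side)
  if (side == "inclusion") .INCLUSION_LABELS else .EXCLUSION_LABELS
}

#' Build the matching prompt for one side of a trial
#'
#' The payload contains the task description, the trial background, the
#' numbered criteria of the requested side only, the sentence-numbered
#' patient note, and the instruction to answer in JSON keyed by 0-based
#' criterion index with, per criterion, the explanation first, then the
#' relevant sentence IDs, then the label.  The explanation-first field
#' order is requested so the label is grounded in generated reasoning.
#' Criteria are passed verbatim: no normalization is applied, so free-form
#' criteria need not follow any format.  Identical inputs yield a
#' byte-identical prompt.
#'
#' @param trial A [trial_record()].
#' @param side `"inclusion"` or `"exclusion"`; that side's criterion list
#'   must be non-empty.
#' @param patient A [patient_note()].
#' @return A single prompt string.
#' @export
build_matching_prompt <- function(trial, side = c("inclusion", "exclusion"), patient) {
  side <- match.arg(side)
  criteria <- if (side == "inclusion") trial$inclusion_criteria else trial$exclusion_criteria
  if (length(criteria) == 0L) .stopf("trial %s has no %s criteria", trial$trial_id, side)
  labels <- eligibility_labels(side)
  bg <- trial$background
  paste0(
    "You are assessing a patient's eligibility for a clinical trial, one ",
    side, " criterion at a time.\n\n",
    "Clinical trial background:\n",
    "Title: ", bg$brief_title, "\n",
    "Conditions: ", paste(bg$conditions, collapse = "; "), "\n",
    "Interventions: ", paste(bg$interventions, collapse = "; "), "\n",
    "Summary: ", bg$brief_summary, "\n\n",
    toupper(substring(side, 1, 1)), substring(side, 2), " criteria:\n",
    paste(sprintf("%d. %s", seq_along(criteria) - 1L, criteria), collapse = "\n"),
    "\n\nPatient note (sentences are numbered; sentence IDs start at 0):\n",
    paste(sprintf("%d. %s", patient$sentences$sentence_id, patient$sentences$text),
          collapse = "\n"),
    "\n\nFor each criterion, first write a brief explanation of the patient's ",
    "relevance to the criterion, then list the IDs of the sentences the ",
    "explanation relies on, then give the eligibility label.\n",
    "The label must be one of: ", paste(sprintf("\"%s\"", labels), collapse = ", "), ".\n",
    "Respond with a JSON object keyed by the criterion number, each value an ",
    "object with fields \"explanation\", \"sentences\", \"label\" in that order.\n"
  )
}

.retry_error <- function(fmt, ...) {
  .stopf(fmt, ..., class = "trialmatchr_retryable_parse_error")
}

#' Construct a single criterion assessment
#'
#' @param criterion_index 0-based index within its side.
#' @param explanation_text Non-empty free text.
#' @param relevant_sentence_ids Integer vector of 0-based sentence IDs.
#' @param label Eligibility label from the side's set.
#' @param side `"inclusion"` or `"exclusion"`.
#' @return A `criterion_assessment` object.
#' @export
criterion_assessment <- function(criterion_index, explanation_text,
                                 relevant_sentence_ids, label,
                                 side = c("inclusion", "exclusion")) {
  side <- match.arg(side)
  if (!label %in% eligibility_labels(side)) {
    .stopf("label %s is not admissible for %s criteria", dQuote(label), side)
  }
  structure(
    list(
      criterion_index = as.integer(criterion_index),
      explanation_text = as.character(explanation_text),
      relevant_sentence_ids = sort(unique(as.integer(relevant_sentence_ids))),
      label = label,
      side = side
    ),
    class = "criterion_assessment"
  )
}

#' Parse and validate a matching response
#'
#' The raw text must be a JSON object keyed `"0"` .. `"n_criteria - 1"`,
#' each value carrying `explanation`, `sentences`, `label`.  Labels outside
#' the side's closed set, missing criteria and malformed JSON raise
#' retryable parse errors.  Sentence IDs outside `[0, n_sentences - 1]`
#' raise an error in strict mode (the default) and are dropped with a
#' warning in lenient mode.
#'
#' @param raw_text Backend response text.
#' @param side `"inclusion"` or `"exclusion"`.
#' @param n_criteria Number of criteria on that side.
#' @param n_sentences Number of sentences in the patient note (`P`).
#' @param strict Reject (vs drop) out-of-range sentence IDs.
#' @return List of [criterion_assessment()] of length `n_criteria`.
#' @export
parse_matching_response <- function(raw_text, side, n_criteria, n_sentences,
                                    strict = TRUE) {
  side <- match.arg(side, c("inclusion", "exclusion"))
  obj <- tryCatch(
    jsonlite::fromJSON(raw_text, simplifyVector = FALSE),
    error = function(e) .retry_error("matching response is not valid JSON: %s", conditionMessage(e))
  )
  if (!is.list(obj)) .retry_error("matching response is not a JSON object")
  out <- vector("list", n_criteria)
  for (k in seq_len(n_criteria)) {
    key <- as.character(k - 1L)
    entry <- obj[[key]]
    if (is.null(entry)) .retry_error("matching response lacks criterion %s", key)
    label <- entry$label
    if (!.is_string(label) || !label %in% eligibility_labels(side)) {
      .retry_error(
        "invalid %s label %s for criterion %s", side,
        if (is.null(label)) "<missing>" else dQuote(as.character(label)), key
      )
    }
    expl <- entry$explanation
    if (!.is_string(expl) || !nzchar(trimws(expl))) {
      .retry_error("missing or empty explanation for criterion %s", key)
    }
    sids <- suppressWarnings(as.integer(unlist(entry$sentences)))
    if (anyNA(sids)) .retry_error("non-integer sentence ID for criterion %s", key)
    bad <- sids < 0L | sids >= n_sentences
    if (any(bad)) {
      if (strict) {
        .retry_error(
          "sentence ID %d out of range [0, %d] for criterion %s",
          sids[bad][1], n_sentences - 1L, key
        )
      }
      warning(sprintf(
        "dropping %d out-of-range sentence ID(s) for %s criterion %s",
        sum(bad), side, key
      ), call. = FALSE)
      sids <- sids[!bad]
    }
    out[[k]] <- criterion_assessment(k - 1L, expl, sids, label, side)
  }
  out
}

#' Assess one patient-trial pair criterion by criterion
#'
#' Makes at most two backend calls (one per non-empty criterion side).  On
#' a retryable parse failure the identical prompt is re-sent up to
#' `retries` times before the error — carrying the raw response — is
#' raised.
#'
#' @param patient A [patient_note()].
#' @param trial A [trial_record()]; must have at least one criterion.
#' @param backend Matching backend.
#' @param retries Re-sends after a parse failure (default 3).
#' @param strict Passed to [parse_matching_response()].
#' @return A `trial_match_result`: list with `patient_id`, `trial_id`,
#'   `inclusion_assessments`, `exclusion_assessments`, `backend_metadata`.
#' @export
match_patient_trial <- function(patient, trial, backend, retries = 3L, strict = TRUE) {
  m <- length(trial$inclusion_criteria)
  n <- length(trial$exclusion_criteria)
  if (m + n == 0L) .stopf("trial %s has no criteria to assess", trial$trial_id)
  P <- nrow(patient$sentences)
  assess_side <- function(side, n_crit) {
    if (n_crit == 0L) return(list())
    prompt <- build_matching_prompt(trial, side, patient)
    req <- backend_request(
      "matching", prompt,
      meta = list(patient_id = patient$patient_id, trial_id = trial$trial_id,
                  side = side, n_criteria = n_crit)
    )
    last_raw <- NULL
    for (attempt in seq_len(retries + 1L)) {
      resp <- complete(backend, req)
      last_raw <- resp$raw_text
      parsed <- tryCatch(
        parse_matching_response(resp$raw_text, side, n_crit, P, strict = strict),
        trialmatchr_retryable_parse_error = function(e) e
      )
      if (!inherits(parsed, "condition")) {
        attr(parsed, "cache_hit") <- resp$cache_hit
        return(parsed)
      }
      last_err <- parsed
    }
    .stopf(
      "matching failed for patient %s, trial %s (%s side) after %d attempts: %s\nraw response: %s",
      patient$patient_id, trial$trial_id, side, retries + 1L,
      conditionMessage(last_err), last_raw
    )
  }
  inc <- assess_side("inclusion", m)
  exc <- assess_side("exclusion", n)
  structure(
    list(
      patient_id = patient$patient_id,
      trial_id = trial$trial_id,
      inclusion_assessments = inc[seq_len(m)],
      exclusion_assessments = exc[seq_len(n)],
      backend_metadata = list(
        backend_id = backend$id,
        cached = isTRUE(attr(inc, "cache_hit")) || isTRUE(attr(exc, "cache_hit"))
      )
    ),
    class = "trial_match_result"
  )
}

#' Assess all run candidates for every patient
#'
#' @param patients List of [patient_note()] objects.
#' @param trials List of [trial_record()] objects.
#' @param run A [run_list()] of candidates per patient (e.g. from
#'   [retrieve_candidates()]); trials with zero criteria are skipped.
#' @param backend Matching backend.
#' @param ... Passed to [match_patient_trial()].
#' @return List of `trial_match_result` objects.
#' @export
match_all <- function(patients, trials, run, backend, ...) {
  trial_by_id <- stats::setNames(trials, vapply(trials, `[[`, character(1), "trial_id"))
  patient_by_id <- stats::setNames(patients, vapply(patients, `[[`, character(1), "patient_id"))
  out <- list()
  for (r in seq_len(nrow(run))) {
    p <- patient_by_id[[run$patient_id[r]]]
    t <- trial_by_id[[run$trial_id[r]]]
    if (is.null(p)) .stopf("run references unknown patient %s", run$patient_id[r])
    if (is.null(t)) .stopf("run references unknown trial %s", run$trial_id[r])
    if (length(t$inclusion_criteria) + length(t$exclusion_criteria) == 0L) next
    out[[length(out) + 1L]] <- match_patient_trial(p, t, backend, ...)
  }
  out
}

.assessment_to_list <- function(a) {
  list(
    criterion_index = a$criterion_index,
    explanation = a$explanation_text,
    sentences = as.list(a$relevant_sentence_ids),
    label = a$label
  )
}

#' Serialize match results to JSONL
#' @param matches List of `trial_match_result` objects.
#' @param path Output path; one JSON object per line.
#' @export
write_matches <- function(matches, path) {
  .write_jsonl(lapply(matches, function(m) {
    list(
      patient_id = m$patient_id,
      trial_id = m$trial_id,
      inclusion = lapply(m$inclusion_assessments, .assessment_to_list),
      exclusion = lapply(m$exclusion_assessments, .assessment_to_list),
      backend = m$backend_metadata$backend_id
    )
  }), path)
}

#' Read match results from JSONL
#' @param path Path written by [write_matches()].
#' @return List of `trial_match_result` objects.
#' @export
read_matches <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    mk <- function(entries, side) {
      lapply(entries, function(a) {
        criterion_assessment(
          a$criterion_index, a$explanation,
          as.integer(unlist(a$sentences)), a$label, side
        )
      })
    }
    structure(
      list(
        patient_id = r$patient_id,
        trial_id = r$trial_id,
        inclusion_assessments = mk(r$inclusion, "inclusion"),
        exclusion_assessments = mk(r$exclusion, "exclusion"),
        backend_metadata = list(backend_id = r$backend, cached = NA)
      ),
      class = "trial_match_result"
    )
  })
}
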