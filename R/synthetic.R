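# Synthetic cohort generator and oracle backend.
#
# The generator plants facts (a diagnosed condition, a serum-marker value,
# a positive or negated history of an exclusion condition) as template
# sentences in each patient note, and builds trials whose criteria
# reference exactly those facts.  Criterion-level ground truth therefore
# follows from the planted facts by construction, every decisive label is
# witnessed by a sentence actually present in the note, and the trial-level
# label is derived from the criterion labels by a fixed precedence rule:
#
#   any "excluded"                        -> excluded
#   else > 1/2 "not enough information"   -> irrelevant
#   else any noinfo or "not included"     -> potential
#   else                                  -> eligible
#
# All randomness is hash-derived from the config seed, so a cohort is
# byte-identical across runs and independent of the global RNG state.

.COHORT_LABELS <- c("eligible", "excluded", "potential", "irrelevant")

#' Configure a synthetic cohort
#'
#' Defaults emulate the structure of the public patient-trial matching
#' collections this package targets: a few dozen patients described by
#' short sentence-segmented narratives, a shared pool of a few hundred
#' trials with explicit inclusion/exclusion criterion lists, and a
#' per-patient mix of eligible, excluded, potential and irrelevant labeled
#' trials with all remaining pairs unlabeled.
#'
#' @param n_patients Number of patients.
#' @param n_trials Number of trials in the shared pool.
#' @param eligible_per_patient,excluded_per_patient,potential_per_patient,irrelevant_per_patient
#'   Per-patient labeled-trial quotas; their sum must not exceed
#'   `n_trials`.
#' @param seed Integer seed driving all generator randomness.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20L, n_trials = 200L,
                          eligible_per_patient = 10L, excluded_per_patient = 6L,
                          potential_per_patient = 2L, irrelevant_per_patient = 2L,
                          seed = 1L) {
  quotas <- c(eligible = eligible_per_patient, excluded = excluded_per_patient,
              potential = potential_per_patient, irrelevant = irrelevant_per_patient)
  if (!.is_count(n_patients) || n_patients < 1) .stopf("n_patients must be positive")
  if (!.is_count(n_trials) || n_trials < 1) .stopf("n_trials must be positive")
  if (!all(vapply(quotas, .is_count, logical(1)))) .stopf("label quotas must be non-negative integers")
  if (sum(quotas) < 1) .stopf("at least one labeled trial per patient is required")
  if (sum(quotas) > n_trials) {
    .stopf("infeasible label mix: %d labeled trials per patient but only %d trials",
           sum(quotas), n_trials)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_trials = as.integer(n_trials),
      quotas = vapply(quotas, as.integer, integer(1)), seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

.cond_name <- function(j) sprintf("disorder d%03dx", j)
.marker_name <- function(j) sprintf("b%03dm", j)
.excl_name <- function(j) sprintf("syndrome e%03dx", j)

.make_trial <- function(j) {
  cond <- .cond_name(j)
  trial_record(
    trial_id = sprintf("NCT%07d", j),
    brief_title = sprintf("A Study of an Investigational Agent for %s", cond),
    conditions = cond,
    interventions = "investigational agent",
    brief_summary = sprintf(
      "This trial evaluates an investigational agent in adults with %s.", cond
    ),
    inclusion_criteria = c(
      "Age of 18 years or older.",
      sprintf("Documented diagnosis of %s.", cond),
      sprintf("Serum marker %s of at least 10 units per liter.", .marker_name(j))
    ),
    exclusion_criteria = sprintf("History of %s.", .excl_name(j))
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with `patients` (list of
#'   [patient_note()]), `trials` (list of [trial_record()]), `truth` (the
#'   ground-truth object consumed by [oracle_backend()] and
#'   [truth_assessments()]), `qrels` (a [qrel_set()] of the per-patient
#'   labeled trials) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) .stopf("config must come from cohort_config()")
  n_labeled <- sum(config$quotas)
  stride <- max(1L, config$n_trials %/% config$n_patients)
  trials <- lapply(seq_len(config$n_trials), .make_trial)
  trial_ids <- vapply(trials, `[[`, character(1), "trial_id")

  patients <- vector("list", config$n_patients)
  facts <- vector("list", config$n_patients)
  qp <- qt <- ql <- character(0)

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("synth-p%02d", p)
    window <- ((p - 1L) * stride + seq_len(n_labeled) - 1L) %% config$n_trials + 1L
    # hash-shuffled label assignment within the window
    slot_labels <- rep(.COHORT_LABELS, times = config$quotas)
    ord <- order(vapply(seq_along(window), function(s) {
      .hash_unif(paste(config$seed, pid, "slot", s))
    }, numeric(1)))
    slot_labels <- slot_labels[ord]

    age <- 18L + as.integer(.hash_string(paste(config$seed, pid, "age")) %% 60)
    sex <- if (.hash_unif(paste(config$seed, pid, "sex")) < 0.5) "man" else "woman"
    sentences <- sprintf("The patient is a %d-year-old %s.", age, sex)
    # per-trial fact bookkeeping: sentence index (0-based) of each witness
    f <- list(cond_sid = list(), marker_sid = list(), marker_val = list(),
              excl_pos_sid = list(), excl_neg_sid = list(), age_sid = 0L,
              label = list())
    for (s in seq_along(window)) {
      j <- window[s]
      lab <- slot_labels[s]
      key <- as.character(j)
      f$label[[key]] <- lab
      if (lab == "irrelevant") next
      sentences <- c(sentences, sprintf(
        "The patient has a documented diagnosis of %s.", .cond_name(j)
      ))
      f$cond_sid[[key]] <- length(sentences) - 1L
      if (lab %in% c("eligible", "excluded")) {
        val <- 12L + as.integer(.hash_string(paste(config$seed, pid, j, "marker")) %% 20)
        sentences <- c(sentences, sprintf(
          "Serum marker %s is %d units per liter.", .marker_name(j), val
        ))
        f$marker_sid[[key]] <- length(sentences) - 1L
        f$marker_val[[key]] <- val
      }
      if (lab == "excluded") {
        sentences <- c(sentences, sprintf(
          "The patient has a known history of %s.", .excl_name(j)
        ))
        f$excl_pos_sid[[key]] <- length(sentences) - 1L
      } else {
        sentences <- c(sentences, sprintf(
          "There is no history of %s.", .excl_name(j)
        ))
        f$excl_neg_sid[[key]] <- length(sentences) - 1L
      }
    }
    note <- patient_note(pid, paste(sentences, collapse = " "))
    if (nrow(note$sentences) != length(sentences)) {
      .stopf("internal error: segmentation did not reproduce planted sentences")
    }
    patients[[p]] <- note
    facts[[p]] <- f
    qp <- c(qp, rep(pid, length(window)))
    qt <- c(qt, trial_ids[window])
    ql <- c(ql, slot_labels)
  }
  names(facts) <- vapply(patients, `[[`, character(1), "patient_id")

  truth <- structure(
    list(config = config, facts = facts, trial_ids = trial_ids),
    class = "cohort_truth"
  )
  cohort <- structure(
    list(
      patients = patients, trials = trials, truth = truth,
      qrels = qrel_set(qp, qt, ql), config = config
    ),
    class = "synthetic_cohort"
  )
  # construction-time audit: assigned labels must equal the labels derived
  # from the planted criterion-level ground truth
  for (r in seq_len(nrow(cohort$qrels))) {
    derived <- truth_trial_label(truth, cohort$qrels$patient_id[r], cohort$qrels$trial_id[r])
    if (derived != cohort$qrels$label[r]) {
      .stopf("internal error: derived label %s != assigned %s", derived, cohort$qrels$label[r])
    }
  }
  cohort
}

.truth_lookup <- function(truth, patient_id, trial_id) {
  f <- truth$facts[[patient_id]]
  if (is.null(f)) .stopf("patient %s is outside the ground truth", patient_id)
  j <- match(trial_id, truth$trial_ids)
  if (is.na(j)) .stopf("trial %s is outside the ground truth", trial_id)
  list(f = f, j = j)
}

#' Ground-truth criterion assessments for one patient-trial pair
#'
#' Derived from the planted facts: the age criterion is always witnessed by
#' the demographic sentence; the diagnosis and marker criteria are
#' `included` when their fact sentence was planted and `not enough
#' information` otherwise; the exclusion criterion is `excluded` /
#' `not excluded` / `not enough information` according to whether a
#' positive history, a negation, or nothing was planted.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param patient_id,trial_id Pair identifiers; unknown IDs error.
#' @return A list with `inclusion` and `exclusion`, each a list of entries
#'   `list(label, sentence_ids)` in criterion order.
#' @export
truth_assessments <- function(truth, patient_id, trial_id) {
  lk <- .truth_lookup(truth, patient_id, trial_id)
  f <- lk$f
  key <- as.character(lk$j)
  crit <- function(sid, label) {
    if (is.null(sid)) list(label = "not enough information", sentence_ids = integer(0))
    else list(label = label, sentence_ids = as.integer(sid))
  }
  exclusion <- if (!is.null(f$excl_pos_sid[[key]])) {
    list(label = "excluded", sentence_ids = as.integer(f$excl_pos_sid[[key]]))
  } else if (!is.null(f$excl_neg_sid[[key]])) {
    list(label = "not excluded", sentence_ids = as.integer(f$excl_neg_sid[[key]]))
  } else {
    list(label = "not enough information", sentence_ids = integer(0))
  }
  list(
    inclusion = list(
      list(label = "included", sentence_ids = f$age_sid),
      crit(f$cond_sid[[key]], "included"),
      crit(f$marker_sid[[key]], "included")
    ),
    exclusion = list(exclusion)
  )
}

#' Ground-truth trial-level label for one patient-trial pair
#'
#' Applies the precedence rule stated in the generator's documentation to
#' the criterion-level ground truth; pairs never planted resolve to
#' `irrelevant`.
#'
#' @inheritParams truth_assessments
#' @return One of `eligible`, `excluded`, `potential`, `irrelevant`.
#' @export
truth_trial_label <- function(truth, patient_id, trial_id) {
  ta <- truth_assessments(truth, patient_id, trial_id)
  labels <- vapply(c(ta$inclusion, ta$exclusion), `[[`, character(1), "label")
  derive_trial_label(labels)
}

#' Derive a trial-level label from criterion labels
#'
#' @param labels Character vector of criterion labels (both sides pooled).
#' @return One of `eligible`, `excluded`, `potential`, `irrelevant`.
#' @export
derive_trial_label <- function(labels) {
  if (any(labels == "excluded")) return("excluded")
  noinfo <- mean(labels == "not enough information")
  if (noinfo > 0.5) return("irrelevant")
  if (noinfo > 0 || any(labels == "not included")) return("potential")
  "eligible"
}

# Fixed aggregation map of the oracle: trial-level truth -> (relevance,
# eligibility), respecting 0 <= R <= 100 and |S| <= R.
.ORACLE_AGG <- list(
  eligible = c(90, 80), excluded = c(80, -80),
  potential = c(70, 10), irrelevant = c(10, 0)
)

#' Deterministic oracle backend built from synthetic ground truth
#'
#' Answers keyword requests with the patient's planted condition terms (in
#' planting order, i.e. importance order), matching requests with the
#' ground-truth labels and witness sentence IDs, and aggregation requests
#' with scores derived from the true trial-level label
#' (eligible (90, 80); excluded (80, -80); potential (70, 10);
#' irrelevant (10, 0)), optionally with seeded jitter that respects the
#' relevance/eligibility constraints.
#'
#' With `noise_rate > 0` each matching label is independently flipped to a
#' uniformly chosen *different* same-side label with that probability; the
#' flips are hash-derived from `(seed, patient, trial, side, criterion)`,
#' so the noisy label stream is identical across runs and independent of
#' query order.  At `noise_rate = 1` every emitted label differs from the
#' truth.
#'
#' @param cohort A [generate_cohort()] result (or its `truth` element
#'   together with `patients`; the full cohort is simplest).
#' @param noise_rate Label-flip probability in [0, 1].
#' @param seed Seed for the noise and jitter streams.
#' @param jitter Half-width of the uniform jitter added to aggregation
#'   scores (0 disables it, the default).
#' @return A `trialmatchr_backend`.
#' @export
oracle_backend <- function(cohort, noise_rate = 0, seed = 1L, jitter = 0) {
  if (!inherits(cohort, "synthetic_cohort")) .stopf("cohort must come from generate_cohort()")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    .stopf("noise_rate must be in [0, 1]")
  }
  truth <- cohort$truth
  id <- sprintf("oracle(noise=%g,seed=%d)", noise_rate, as.integer(seed))

  maybe_flip <- function(label, side, key) {
    if (noise_rate > 0 && .hash_unif(paste(seed, key, "flip")) < noise_rate) {
      others <- setdiff(eligibility_labels(side), label)
      others[.hash_pick(paste(seed, key), length(others))]
    } else {
      label
    }
  }

  handler <- function(request) {
    meta <- request$meta
    if (request$purpose == "keywords") {
      f <- truth$facts[[meta$patient_id]]
      if (is.null(f)) .stopf("patient %s is outside the ground truth", meta$patient_id)
      planted <- names(f$cond_sid)[order(unlist(f$cond_sid))]
      kws <- vapply(as.integer(planted), .cond_name, character(1))
      if (length(kws) == 0L) kws <- "adult patient"
      return(as.character(jsonlite::toJSON(kws)))
    }
    if (request$purpose == "matching") {
      ta <- truth_assessments(truth, meta$patient_id, meta$trial_id)
      side <- meta$side
      entries <- ta[[side]]
      out <- list()
      for (k in seq_along(entries)) {
        e <- entries[[k]]
        key <- paste(meta$patient_id, meta$trial_id, side, k - 1L)
        lab <- maybe_flip(e$label, side, key)
        out[[as.character(k - 1L)]] <- list(
          explanation = sprintf(
            "Criterion %d was compared against the planted patient facts; assessment: %s.",
            k - 1L, lab
          ),
          sentences = as.list(e$sentence_ids),
          label = lab
        )
      }
      return(as.character(jsonlite::toJSON(out, auto_unbox = TRUE)))
    }
    # aggregation
    lab <- truth_trial_label(truth, meta$patient_id, meta$trial_id)
    base <- .ORACLE_AGG[[lab]]
    r <- base[1]; s <- base[2]
    if (jitter > 0) {
      key <- paste(seed, meta$patient_id, meta$trial_id)
      r <- r + (2 * .hash_unif(paste(key, "rjit")) - 1) * jitter
      s <- s + (2 * .hash_unif(paste(key, "sjit")) - 1) * jitter
      r <- min(max(r, 0), 100)
      s <- sign(s) * min(abs(s), r)
    }
    as.character(jsonlite::toJSON(list(relevance = r, eligibility = s), auto_unbox = TRUE))
  }
  make_backend(id, handler)
}

#' Write a synthetic cohort to disk
#'
#' Writes `patients.jsonl`, `trials.jsonl`, `qrels.txt` (with the extended
#' label map: 0 irrelevant, 1 excluded, 2 eligible, 3 potential) and
#' `ground_truth.jsonl` (one line per labeled pair with the criterion-level
#' truth) into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_patients(cohort$patients, file.path(dir, "patients.jsonl"))
  write_trials(cohort$trials, file.path(dir, "trials.jsonl"))
  write_qrels(cohort$qrels, file.path(dir, "qrels.txt"))
  gt <- lapply(seq_len(nrow(cohort$qrels)), function(r) {
    pid <- cohort$qrels$patient_id[r]; tid <- cohort$qrels$trial_id[r]
    ta <- truth_assessments(cohort$truth, pid, tid)
    list(
      patient_id = pid, trial_id = tid, label = cohort$qrels$label[r],
      inclusion = lapply(ta$inclusion, function(e) {
        list(label = e$label, sentences = as.list(e$sentence_ids))
      }),
      exclusion = lapply(ta$exclusion, function(e) {
        list(label = e$label, sentences = as.list(e$sentence_ids))
      })
    )
  })
  .write_jsonl(gt, file.path(dir, "ground_truth.jsonl"))
  invisible(dir)
}
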