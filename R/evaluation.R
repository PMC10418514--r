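# Graded information-retrieval metrics for patient-trial matching.
#
# Relevance grades: eligible -> 2, excluded or potential -> 1, irrelevant
# or unlabeled -> 0.  Note two deliberate conventions, both documented on
# the functions below: P@k here is the graded, max-grade-normalized
# variant (sum of top-k grades divided by 2k), not classical binary
# precision; and a ranked list whose ideal DCG is zero scores NDCG = 0.

#' Map an eligibility label to its relevance grade
#'
#' @param label Character vector over `eligible`, `excluded`, `potential`,
#'   `irrelevant`, `unlabeled`.
#' @return Integer grades in \{0, 1, 2\}: eligible is 2, excluded and
#'   potential are 1, irrelevant and unlabeled are 0.
#' @export
map_relevance <- function(label) {
  grades <- c(eligible = 2L, excluded = 1L, potential = 1L,
              irrelevant = 0L, unlabeled = 0L)
  bad <- setdiff(unique(label), names(grades))
  if (length(bad)) .stopf("unknown eligibility label(s): %s", paste(bad, collapse = ", "))
  unname(grades[label])
}

.check_rel <- function(r) {
  if (length(r) && !all(r %in% 0:2)) .stopf("relevance grades must be in {0, 1, 2}")
  as.numeric(r)
}

#' Recall at depth k
#'
#' Sum of the top-k relevance grades divided by `R_total`, the summed
#' relevance of the whole considered collection for this patient.
#'
#' @param ranked_relevances Relevance grades in rank order.
#' @param R_total Total collection relevance; must be positive.
#' @param k Depth, at least 1.
#' @return Recall in [0, 1].
#' @export
recall_at_k <- function(ranked_relevances, R_total, k) {
  r <- .check_rel(ranked_relevances)
  if (!.is_count(k) || k < 1) .stopf("k must be a positive integer")
  if (!is.numeric(R_total) || length(R_total) != 1L || R_total <= 0) {
    .stopf("recall is undefined when the collection has zero total relevance")
  }
  sum(utils::head(r, k)) / R_total
}

.dcg <- function(r, k) {
  r <- utils::head(r, k)
  if (length(r) == 0L) return(0)
  sum(r / log2(seq_along(r) + 1))
}

#' Normalized discounted cumulative gain at depth k
#'
#' `DCG@k = sum_{x=1..k} r_x / log2(x + 1)`, normalized by the DCG of the
#' ideal (grade-descending) ordering.  When the ideal DCG is zero (no
#' relevant trial exists) the result is defined as 0.
#'
#' @param ranked_relevances Relevance grades in rank order.
#' @param ideal_relevances The same multiset of grades sorted descending
#'   (or any vector whose descending sort is the ideal ranking).
#' @param k Depth.
#' @return NDCG in [0, 1].
#' @export
ndcg_at_k <- function(ranked_relevances, ideal_relevances, k) {
  r <- .check_rel(ranked_relevances)
  ideal <- sort(.check_rel(ideal_relevances), decreasing = TRUE)
  if (!.is_count(k) || k < 1) .stopf("k must be a positive integer")
  idcg <- .dcg(ideal, k)
  if (idcg == 0) return(0)
  .dcg(r, k) / idcg
}

#' Graded precision at depth k
#'
#' Implemented as printed in the evaluation protocol this package follows:
#' `P@k = sum_{x=1..k} r_x / (max_grade * k)` with `max_grade = 2` — a
#' graded, normalized variant that differs from classical binary P@k.
#' Lists shorter than `k` are padded with zeros.
#'
#' @param ranked_relevances Relevance grades in rank order.
#' @param k Depth.
#' @param max_grade Largest possible grade (2 for the three-level labels).
#' @return Normalized precision in [0, 1].
#' @export
precision_at_k <- function(ranked_relevances, k, max_grade = 2) {
  r <- .check_rel(ranked_relevances)
  if (!.is_count(k) || k < 1) .stopf("k must be a positive integer")
  sum(utils::head(r, k)) / (max_grade * k)
}

#' Area under the ROC curve (Mann-Whitney, midrank ties)
#'
#' Probability that a uniformly drawn positive outscores a uniformly drawn
#' negative, with ties counted one half.  For the trial-excluding task the
#' positive class is "excluded" and callers must orient scores so that
#' higher means more likely excluded.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) .stopf("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) .stopf("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.parse_metric <- function(m) {
  if (m == "auroc") return(list(name = "auroc", k = NA_integer_))
  parts <- regmatches(m, regexec("^(ndcg|p|recall)@([0-9]+)$", m))[[1]]
  if (length(parts) != 3L) .stopf("unknown metric: %s (use e.g. ndcg@10, p@10, recall@500, auroc)", m)
  list(name = parts[2], k = as.integer(parts[3]))
}

#' Evaluate a run against eligibility judgments
#'
#' Rank metrics (`ndcg@k`, `p@k`, `recall@k`) are computed per patient over
#' the run's ranked trials graded through [map_relevance()] (trials absent
#' from the qrels count as unlabeled, grade 0) and macro-averaged with
#' equal patient weight.  Patients with no labeled trial are skipped with a
#' warning.  `auroc` evaluates the trial-excluding task pooled over all
#' (patient, trial) pairs labeled `excluded` (positive) or `eligible`
#' (negative); `potential`, `irrelevant` and unlabeled pairs are dropped.
#' Run scores rank by eligibility, so the AUROC uses their negation.
#'
#' @param run A [run_list()].
#' @param qrels A [qrel_set()].
#' @param metrics Character vector, e.g. `c("ndcg@10", "p@10", "recall@500", "auroc")`.
#' @return A list with `per_patient` (data.frame of per-patient rank
#'   metrics) and `macro` (named numeric vector of means, plus pooled
#'   `auroc` when requested).
#' @export
evaluate_run <- function(run, qrels, metrics = c("ndcg@10", "p@10")) {
  if (!length(intersect(unique(run$patient_id), unique(qrels$patient_id)))) {
    .stopf("run and qrels share no patient IDs")
  }
  specs <- lapply(metrics, .parse_metric)
  rank_specs <- Filter(function(s) s$name != "auroc", specs)
  want_auroc <- any(vapply(specs, function(s) s$name == "auroc", logical(1)))
  qkey <- paste(qrels$patient_id, qrels$trial_id, sep = "\x1f")
  qlab <- stats::setNames(qrels$label, qkey)
  per_patient <- list()
  for (pid in sort(unique(run$patient_id))) {
    sub <- run[run$patient_id == pid, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    plabels <- qrels$label[qrels$patient_id == pid]
    if (length(plabels) == 0L) {
      warning(sprintf("patient %s has no labeled trials; skipped", pid), call. = FALSE)
      next
    }
    key <- paste(pid, sub$trial_id, sep = "\x1f")
    lab <- qlab[key]
    lab[is.na(lab)] <- "unlabeled"
    rel <- map_relevance(unname(lab))
    ideal <- map_relevance(plabels)
    R_total <- sum(ideal)
    row <- list(patient_id = pid)
    for (s in rank_specs) {
      val <- switch(s$name,
        ndcg = ndcg_at_k(rel, ideal, s$k),
        p = precision_at_k(rel, s$k),
        recall = if (R_total > 0) recall_at_k(rel, R_total, s$k) else NA_real_
      )
      row[[sprintf("%s@%d", s$name, s$k)]] <- val
    }
    per_patient[[length(per_patient) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  pp <- do.call(rbind, per_patient)
  macro <- vapply(
    setdiff(names(pp), "patient_id"),
    function(cn) mean(pp[[cn]], na.rm = TRUE), numeric(1)
  )
  if (want_auroc) {
    key <- paste(run$patient_id, run$trial_id, sep = "\x1f")
    lab <- qlab[key]
    sel <- !is.na(lab) & lab %in% c("excluded", "eligible")
    if (!any(sel)) .stopf("no excluded/eligible labeled pairs in the run for AUROC")
    macro <- c(macro, auroc = auroc(-run$score[sel], lab[sel] == "excluded"))
  }
  list(per_patient = pp, macro = macro)
}
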