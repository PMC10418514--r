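test_that("cohort generation is seed-deterministic down to the bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cohort_config(n_patients = 3, n_trials = 20,
                                             eligible_per_patient = 2,
                                             excluded_per_patient = 2,
                                             potential_per_patient = 1,
                                             irrelevant_per_patient = 1, seed = 13)), d1)
  write_cohort(generate_cohort(cohort_config(n_patients = 3, n_trials = 20,
                                             eligible_per_patient = 2,
                                             excluded_per_patient = 2,
                                             potential_per_patient = 1,
                                             irrelevant_per_patient = 1, seed = 13)), d2)
  for (f in c("patients.jsonl", "trials.jsonl", "qrels.txt", "ground_truth.jsonl")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the cohort
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(cohort_config(n_patients = 3, n_trials = 20,
                                             eligible_per_patient = 2,
                                             excluded_per_patient = 2,
                                             potential_per_patient = 1,
                                             irrelevant_per_patient = 1, seed = 14)), d3)
  expect_false(identical(readLines(file.path(d1, "patients.jsonl")),
                         readLines(file.path(d3, "patients.jsonl"))))
})

test_that("qrels contain exactly the configured label quotas per patient", {
  co <- generate_cohort(cohort_config(n_patients = 5, n_trials = 60,
                                      eligible_per_patient = 10,
                                      excluded_per_patient = 4,
                                      potential_per_patient = 3,
                                      irrelevant_per_patient = 2, seed = 2))
  for (pid in unique(co$qrels$patient_id)) {
    tab <- table(co$qrels$label[co$qrels$patient_id == pid])
    expect_equal(unname(tab[["eligible"]]), 10L)
    expect_equal(unname(tab[["excluded"]]), 4L)
    expect_equal(unname(tab[["potential"]]), 3L)
    expect_equal(unname(tab[["irrelevant"]]), 2L)
  }
  expect_error(cohort_config(n_trials = 10, eligible_per_patient = 20),
               "infeasible")
})

test_that("every decisive criterion label is witnessed by a planted sentence", {
  co <- tiny_cohort()
  token_of <- list(
    "1" = function(j) sprintf("The patient is a"),                      # age sentence
    "2" = function(j) sprintf("documented diagnosis of disorder d%03dx", j),
    "3" = function(j) sprintf("marker b%03dm", j)
  )
  trial_ids <- vapply(co$trials, `[[`, character(1), "trial_id")
  for (r in seq_len(nrow(co$qrels))) {
    pid <- co$qrels$patient_id[r]; tid <- co$qrels$trial_id[r]
    pat <- Filter(function(p) p$patient_id == pid, co$patients)[[1]]
    j <- match(tid, trial_ids)
    ta <- truth_assessments(co$truth, pid, tid)
    for (k in seq_along(ta$inclusion)) {
      e <- ta$inclusion[[k]]
      if (e$label == "included") {
        expect_gte(length(e$sentence_ids), 1L)
        sent <- pat$sentences$text[pat$sentences$sentence_id %in% e$sentence_ids]
        expect_true(any(grepl(token_of[[as.character(k)]](j), sent, fixed = TRUE)))
      } else {
        expect_length(e$sentence_ids, 0L)
      }
    }
    e <- ta$exclusion[[1]]
    if (e$label != "not enough information") {
      sent <- pat$sentences$text[pat$sentences$sentence_id %in% e$sentence_ids]
      expect_true(any(grepl(sprintf("syndrome e%03dx", j), sent, fixed = TRUE)))
    }
  }
})

test_that("trial-level labels follow the stated consistency rules", {
  expect_equal(derive_trial_label(c("included", "included", "excluded")), "excluded")
  expect_equal(derive_trial_label(c("included", rep("not enough information", 3))), "irrelevant")
  expect_equal(derive_trial_label(c("included", "included", "not enough information",
                                    "not excluded")), "potential")
  expect_equal(derive_trial_label(c("included", "included", "not excluded")), "eligible")
  expect_equal(derive_trial_label(c("included", "not included", "not excluded")), "potential")

  co <- tiny_cohort()
  for (r in seq_len(nrow(co$qrels))) {
    derived <- truth_trial_label(co$truth, co$qrels$patient_id[r], co$qrels$trial_id[r])
    expect_equal(derived, co$qrels$label[r])
    ta <- truth_assessments(co$truth, co$qrels$patient_id[r], co$qrels$trial_id[r])
    labs <- vapply(c(ta$inclusion, ta$exclusion), `[[`, character(1), "label")
    if (co$qrels$label[r] == "eligible") {
      expect_false(any(labs %in% c("not included", "excluded")))
    }
    if (co$qrels$label[r] == "excluded") expect_true(any(labs == "excluded"))
    if (co$qrels$label[r] == "irrelevant") {
      expect_gt(mean(labs == "not enough information"), 0.5)
    }
  }
})

test_that("oracle noise flips labels at the configured rate, always to a different label", {
  co <- tiny_cohort()
  pid <- co$qrels$patient_id[1]; tid <- co$qrels$trial_id[1]
  pat <- Filter(function(p) p$patient_id == pid, co$patients)[[1]]
  trial <- co$trials[[match(tid, vapply(co$trials, `[[`, character(1), "trial_id"))]]
  truth_labels <- function(res) {
    vapply(c(res$inclusion_assessments, res$exclusion_assessments), `[[`, character(1), "label")
  }
  ta <- truth_assessments(co$truth, pid, tid)
  want <- vapply(c(ta$inclusion, ta$exclusion), `[[`, character(1), "label")

  noiseless <- match_patient_trial(pat, trial, oracle_backend(co, noise_rate = 0))
  expect_equal(truth_labels(noiseless), want)

  # noise 1: every emitted label differs from the truth, on every pair
  full <- oracle_backend(co, noise_rate = 1, seed = 3)
  for (r in 1:6) {
    p <- Filter(function(x) x$patient_id == co$qrels$patient_id[r], co$patients)[[1]]
    t <- co$trials[[match(co$qrels$trial_id[r], vapply(co$trials, `[[`, character(1), "trial_id"))]]
    res <- match_patient_trial(p, t, full)
    tw <- truth_assessments(co$truth, p$patient_id, t$trial_id)
    wl <- vapply(c(tw$inclusion, tw$exclusion), `[[`, character(1), "label")
    gl <- truth_labels(res)
    expect_true(all(gl != wl))
    # flipped labels stay inside the side-specific sets
    expect_true(all(gl[1:3] %in% eligibility_labels("inclusion")))
    expect_true(all(gl[4] %in% eligibility_labels("exclusion")))
  }

  # fixed seed: identical noisy stream across independent backend instances
  a <- match_patient_trial(pat, trial, oracle_backend(co, noise_rate = 0.5, seed = 9))
  b <- match_patient_trial(pat, trial, oracle_backend(co, noise_rate = 0.5, seed = 9))
  expect_equal(truth_labels(a), truth_labels(b))
})

test_that("oracle aggregation scores follow the fixed trial-label map", {
  co <- tiny_cohort()
  be <- oracle_backend(co)
  map <- list(eligible = c(90, 80), excluded = c(80, -80),
              potential = c(70, 10), irrelevant = c(10, 0))
  for (r in c(1, 3, 5, 7)) {
    pid <- co$qrels$patient_id[r]; tid <- co$qrels$trial_id[r]
    pat <- Filter(function(p) p$patient_id == pid, co$patients)[[1]]
    trial <- co$trials[[match(tid, vapply(co$trials, `[[`, character(1), "trial_id"))]]
    res <- match_patient_trial(pat, trial, be)
    agg <- llm_aggregate(pat, trial, res, be)
    want <- map[[co$qrels$label[r]]]
    expect_equal(agg$relevance_score, want[1])
    expect_equal(agg$eligibility_score, want[2])
  }
  # queries outside the ground truth error
  ghost <- patient_note("ghost", "Nothing known.")
  expect_error(
    match_patient_trial(ghost, co$trials[[1]], be, retries = 0),
    "outside the ground truth"
  )
})
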