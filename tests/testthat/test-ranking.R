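test_that("linear aggregation matches hand-computed percentages", {
  r1 <- fake_match_result(c("included", "included", "not included", "not applicable"),
                          character(0))
  l1 <- linear_aggregate(r1)
  expect_equal(l1$M_prime, 3L)
  expect_equal(l1$pct_met_inclusion, 2 / 3)
  expect_equal(l1$pct_unmet_inclusion, 1 / 3)
  expect_equal(l1$pct_noinfo_inclusion, 0)

  r2 <- fake_match_result(character(0), c("excluded", "not enough information"))
  l2 <- linear_aggregate(r2)
  expect_equal(l2$N_prime, 2L)
  expect_equal(l2$pct_met_exclusion, 1 / 2)
  expect_equal(l2$pct_unmet_exclusion, 0)
  expect_equal(l2$pct_noinfo_exclusion, 1 / 2)

  r3 <- fake_match_result(rep("not applicable", 3), rep("not applicable", 2))
  l3 <- linear_aggregate(r3)
  expect_equal(l3$M_prime, 0L)
  expect_equal(l3$N_prime, 0L)
  expect_equal(
    unlist(l3[c("pct_met_inclusion", "pct_unmet_inclusion", "pct_noinfo_inclusion",
                "pct_met_exclusion", "pct_unmet_exclusion", "pct_noinfo_exclusion")]),
    rep(0, 6), ignore_attr = TRUE
  )
})

test_that("percentages sum to one per side whenever the denominator is positive", {
  inc_set <- eligibility_labels("inclusion")
  exc_set <- eligibility_labels("exclusion")
  set.seed(99)
  for (rep in 1:400) {
    m <- sample(0:6, 1); n <- sample(0:6, 1)
    if (m + n == 0) next
    res <- fake_match_result(sample(inc_set, m, replace = TRUE),
                             sample(exc_set, n, replace = TRUE))
    l <- linear_aggregate(res)
    pct <- unlist(l[1:6])
    expect_true(all(pct >= 0 & pct <= 1))
    if (l$M_prime > 0) {
      expect_equal(l$pct_met_inclusion + l$pct_unmet_inclusion + l$pct_noinfo_inclusion, 1)
    } else {
      expect_equal(unname(pct[1:3]), rep(0, 3))
    }
    if (l$N_prime > 0) {
      expect_equal(l$pct_met_exclusion + l$pct_unmet_exclusion + l$pct_noinfo_exclusion, 1)
    } else {
      expect_equal(unname(pct[4:6]), rep(0, 3))
    }
  }
})

test_that("aggregate score validation clamps out-of-range backend values with a warning", {
  ok <- aggregate_scores(100, 100)
  expect_equal(ok$relevance_score, 100)
  expect_equal(ok$eligibility_score, 100)

  expect_warning(cl <- aggregate_scores(50, 80), "clamped")
  expect_equal(cl$eligibility_score, 50)
  expect_warning(cl2 <- aggregate_scores(50, -80), "clamped")
  expect_equal(cl2$eligibility_score, -50)

  # clamping cascade: relevance first, then eligibility against it
  expect_warning(cl3 <- aggregate_scores(-5, 0), "clamped")
  expect_equal(cl3$relevance_score, 0)
  expect_equal(cl3$eligibility_score, 0)
  expect_warning(expect_warning(cl4 <- aggregate_scores(120, 110)))
  expect_equal(cl4$relevance_score, 100)
  expect_equal(cl4$eligibility_score, 100)
})

test_that("combination score matches hand arithmetic", {
  lin <- function(met, unmet, met_excl) {
    structure(list(pct_met_inclusion = met, pct_unmet_inclusion = unmet,
                   pct_noinfo_inclusion = 0, pct_met_exclusion = met_excl,
                   pct_unmet_exclusion = 0, pct_noinfo_exclusion = 0,
                   M_prime = 1L, N_prime = 1L), class = "linear_scores")
  }
  agg <- function(r, s) structure(list(relevance_score = r, eligibility_score = s),
                                  class = "aggregate_scores")
  expect_equal(combine_scores(lin(1, 0, 0), agg(80, 60)), 2.4)
  expect_equal(combine_scores(lin(0.5, 0.25, 0.5), agg(50, -50)), -1.5)
  expect_equal(combine_scores(lin(0, 0, 0), agg(0, 0)), 0)
  # linear-only variant keeps the first three terms
  expect_equal(combine_scores(lin(0.5, 0.25, 0.5), NULL), 0.5 - 1 - 1)
  # un-normalized mode is available
  expect_equal(combine_scores(lin(1, 0, 0), agg(80, 60), normalize_llm = FALSE), 141)
})

test_that("combination is monotone over a perturbation grid", {
  agg <- function(r, s) structure(list(relevance_score = r, eligibility_score = s),
                                  class = "aggregate_scores")
  lin <- function(met, unmet, met_excl) {
    structure(list(pct_met_inclusion = met, pct_unmet_inclusion = unmet,
                   pct_noinfo_inclusion = 0, pct_met_exclusion = met_excl,
                   pct_unmet_exclusion = 0, pct_noinfo_exclusion = 0,
                   M_prime = 1L, N_prime = 1L), class = "linear_scores")
  }
  grid <- expand.grid(met = c(0, 0.3, 1), unmet = c(0, 0.4), excl = c(0, 0.6),
                      rel = c(0, 50, 100), elig = c(-50, 0, 50))
  for (g in seq_len(nrow(grid))) {
    # restrict the grid to feasible (relevance, eligibility) pairs
    e0 <- max(min(grid$elig[g], grid$rel[g]), -grid$rel[g])
    base <- combine_scores(lin(grid$met[g], grid$unmet[g], grid$excl[g]),
                           agg(grid$rel[g], e0))
    # non-decreasing in met inclusion, relevance, eligibility
    expect_gte(combine_scores(lin(min(grid$met[g] + 0.1, 1), grid$unmet[g], grid$excl[g]),
                              agg(grid$rel[g], e0)), base)
    expect_gte(combine_scores(lin(grid$met[g], grid$unmet[g], grid$excl[g]),
                              agg(min(grid$rel[g] + 10, 100), e0)), base)
    expect_gte(combine_scores(lin(grid$met[g], grid$unmet[g], grid$excl[g]),
                              agg(grid$rel[g], min(e0 + 10, grid$rel[g]))), base)
    # non-increasing in the two indicator arguments
    expect_lte(combine_scores(lin(grid$met[g], grid$unmet[g] + 0.1, grid$excl[g]),
                              agg(grid$rel[g], e0)), base)
    expect_lte(combine_scores(lin(grid$met[g], grid$unmet[g], grid$excl[g] + 0.1),
                              agg(grid$rel[g], e0)), base)
  }
})

test_that("llm_aggregate validates backend output and clamps with a warning", {
  co <- tiny_cohort()
  pat <- co$patients[[1]]
  trial <- co$trials[[1]]
  res <- fake_match_result(c("included", "included", "included"), "not excluded",
                           patient_id = pat$patient_id, trial_id = trial$trial_id)
  be_ok <- mock_backend(function(req) '{"relevance": 100, "eligibility": 100}')
  a <- llm_aggregate(pat, trial, res, be_ok)
  expect_equal(a$relevance_score, 100)
  be_bad <- mock_backend(function(req) '{"relevance": 50, "eligibility": 80}')
  expect_warning(b <- llm_aggregate(pat, trial, res, be_bad), "clamped")
  expect_equal(b$eligibility_score, 50)
  be_junk <- mock_backend(function(req) "no json at all")
  expect_error(llm_aggregate(pat, trial, res, be_junk, retries = 1), "after 2 attempts")
})

test_that("rank_trials orders by key with trial-id tie-breaks and 1-based ranks", {
  scores <- data.frame(
    patient_id = rep("p1", 3), trial_id = c("NCT2", "NCT1", "NCT3"),
    pct_met_inclusion = c(0.5, 0.5, 1), pct_unmet_inclusion = 0,
    pct_noinfo_inclusion = 0, pct_met_exclusion = 0, pct_unmet_exclusion = 0,
    pct_noinfo_exclusion = 0, M_prime = 2L, N_prime = 0L,
    relevance = c(90, 70, 90), eligibility = c(80, -70, 80),
    combination = c(2.2, 0.5, 2.7), stringsAsFactors = FALSE
  )
  run <- rank_trials(scores, "combination")
  expect_equal(run$trial_id, c("NCT3", "NCT2", "NCT1"))
  expect_equal(run$rank, 1:3)
  # equal scores break ties by ascending trial id
  tied <- rank_trials(scores, "pct_met_inclusion")
  expect_equal(tied$trial_id, c("NCT3", "NCT1", "NCT2"))
  # eligibility key: (90, 80) outranks (70, -70)
  el <- rank_trials(scores[1:2, ], "eligibility")
  expect_equal(el$trial_id[1], "NCT2")
  expect_error(rank_trials(scores, "nonsense"), "unknown ranking key")
})
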