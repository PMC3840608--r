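test_that("prevalence ranking counts distinct patients with ties by code", {
  ev <- rbind(tiny_events(1:50, "pharmacy", "A"),
              tiny_events(1:40, "pharmacy", "B"),
              tiny_events(1:10, "pharmacy", "C"))
  expect_equal(rank_prevalent_codes(ev, "pharmacy", 2), c("A", "B"))
  expect_equal(rank_prevalent_codes(ev, "pharmacy", 10), c("A", "B", "C"))
  # tie broken lexicographically
  tie <- rbind(tiny_events(1:50, "pharmacy", "B"),
               tiny_events(1:50, "pharmacy", "A"))
  expect_equal(rank_prevalent_codes(tie, "pharmacy", 1), "A")
  # multiple claims of one patient count once
  dup <- rbind(tiny_events(c(1, 1, 1), "pharmacy", "A"),
               tiny_events(1:2, "pharmacy", "B"))
  expect_equal(rank_prevalent_codes(dup, "pharmacy", 1), "B")
})

test_that("recurrence cutoffs follow the median / nearest-rank rules", {
  expect_equal(recurrence_thresholds(c(1, 2, 3, 10)),
               c(sporadic = 3, frequent = 3))
  expect_equal(recurrence_thresholds(c(1, 1, 1)), c(sporadic = 1, frequent = 1))
  expect_equal(recurrence_thresholds(c(5, 5, 5, 5)), c(sporadic = 5, frequent = 5))
  expect_error(recurrence_thresholds(numeric()), "no occurrence")
})

test_that("recurrence expansion applies thresholds and drops duplicates", {
  cands <- expand_recurrence_indicators("X", "pharmacy",
                                        patient_ids = c(1L, 2L, 3L, 4L),
                                        counts = c(1, 2, 3, 10),
                                        thresholds = c(sporadic = 3, frequent = 4))
  levs <- vapply(cands, `[[`, character(1), "recurrence_level")
  expect_equal(levs, c("once", "sporadic", "frequent"))
  # a patient with 2 occurrences qualifies only for "once"
  expect_true(2L %in% cands[[1]]$patients)
  expect_false(2L %in% cands[[2]]$patients)
  expect_false(2L %in% cands[[3]]$patients)
  # collapsed thresholds: identical sets keep the least restrictive label
  one <- expand_recurrence_indicators("X", "pharmacy", 1:3, c(1, 1, 1),
                                      c(sporadic = 1, frequent = 1))
  expect_length(one, 1L)
  expect_equal(one[[1]]$recurrence_level, "once")
})

test_that("screening enforces the patient floor and zero-cell rules", {
  cand <- data.frame(n_patients = c(99L, 100L, 500L, 500L, 500L),
                     rr_ce = c(2, 2, 0, 2, Inf),
                     rr_cd = c(2, 2, 2, 0, 2))
  out <- screen_candidates(cand, min_patients = 100L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_patients, 100L)   # boundary inclusive
  counts <- attr(out, "screen_counts")
  expect_equal(unname(counts["below_min_patients"]), 1L)
  expect_equal(unname(counts["undefined_exposure_ratio"]), 2L)
  expect_equal(unname(counts["undefined_outcome_ratio"]), 1L)
  # min_patients = 0 disables the floor
  expect_equal(nrow(screen_candidates(cand, 0L)), 2L)
})

test_that("associations match hand-computed contingency tables", {
  # 20 patients: 8 exposed; covariate in 4 exposed, 2 unexposed;
  # outcome in 3 covariate-positive and 2 covariate-negative patients
  exposed <- rep(c(1L, 0L), c(8L, 12L))
  cov <- c(rep(1L, 4L), rep(0L, 4L), rep(1L, 2L), rep(0L, 10L))
  outcome <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L,
               1L, 1L, rep(0L, 8L))
  a <- covariate_associations(cov, exposed, outcome)
  expect_equal(a$p_c1, 4 / 8)
  expect_equal(a$p_c0, 2 / 12)
  expect_equal(a$rr_ce, (4 / 8) / (2 / 12))
  expect_equal(a$rr_cd, (3 / 6) / (2 / 14))
  expect_equal(a$prevalence, 6 / 20)
  # covariate independent of outcome in a constructed table
  b <- covariate_associations(rep(c(1, 0), 10),
                              rep(c(1, 0), each = 10),
                              rep(c(1, 1, 0, 0), 5))
  expect_equal(b$rr_cd, 1)
})

test_that("the Bross multiplier matches direct formula evaluation", {
  expect_equal(bross_bias_multiplier(0.2, 0.1, 3.8),
               (0.2 * 2.8 + 1) / (0.1 * 2.8 + 1))
  expect_equal(bross_bias_multiplier(0.3, 0.1, 1), 1)
  expect_equal(bross_bias_multiplier(0.2, 0.2, 3.8), 1)
  # protective associations are inverted to r >= 1 first
  expect_equal(bross_bias_multiplier(0.2, 0.1, 1 / 3.8),
               bross_bias_multiplier(0.2, 0.1, 3.8))
  expect_error(bross_bias_multiplier(0.2, 0.1, 0), "positive")
  expect_error(bross_bias_multiplier(1.2, 0.1, 2), "prevalences")
})

test_that("selection sorts by |ln B| with deterministic tie-breaks", {
  pr <- data.frame(abs_log_bias = c(0.5, 0.2, 0.9),
                   dimension = "pharmacy", code = c("A", "B", "C"),
                   recurrence_level = "once", stringsAsFactors = FALSE)
  out <- select_top_covariates(pr, 2)
  expect_equal(out$code, c("C", "A"))
  expect_equal(out$rank, 1:2)
  expect_equal(nrow(select_top_covariates(pr, 10)), 3L)
  tie <- data.frame(abs_log_bias = 0.4, dimension = "pharmacy",
                    code = c("B", "A"), recurrence_level = "once",
                    stringsAsFactors = FALSE)
  expect_equal(select_top_covariates(tie, 2)$code, c("A", "B"))
})

test_that("the engine is deterministic end to end", {
  inst <- random_instance(n = 150L, n_codes = 10L, seed = 21L)
  cfg <- hdps_config(min_patients = 10L, k_select = 15L)
  a <- hdps_covariates(inst$events, inst$cohort, cfg)
  b <- hdps_covariates(inst$events, inst$cohort, cfg)
  expect_identical(a$selected, b$selected)
})

test_that("raising the patient floor never adds candidates", {
  inst <- random_instance(n = 200L, n_codes = 15L, seed = 22L)
  pools <- lapply(c(0L, 20L, 50L, 120L), function(m) {
    res <- hdps_covariates(inst$events, inst$cohort,
                           hdps_config(min_patients = m))
    selection_keys(res$selected)
  })
  for (i in 2:length(pools))
    expect_true(all(pools[[i]] %in% pools[[i - 1]]))
})

test_that("selection matches the brute-force oracle on small instances", {
  for (seed in c(31L, 32L, 33L, 34L, 35L)) {
    inst <- random_instance(n = 250L, n_codes = sample(5:20, 1), seed = seed)
    for (m in c(0L, 25L)) {
      ours <- hdps_covariates(inst$events, inst$cohort,
                              hdps_config(min_patients = m, k_select = 10L))
      oracle <- oracle_hdps_selection(inst$events, inst$cohort,
                                      min_patients = m, k_select = 10L)
      expect_equal(selection_keys(ours$selected), selection_keys(oracle))
      expect_equal(ours$selected$abs_log_bias, oracle$abs_log_bias,
                   tolerance = 1e-12)
    }
  }
})

test_that("the indicator matrix reproduces per-candidate patient sets", {
  inst <- random_instance(n = 120L, n_codes = 8L, seed = 41L)
  res <- hdps_covariates(inst$events, inst$cohort,
                         hdps_config(min_patients = 5L, k_select = 30L))
  X <- build_indicator_matrix(inst$events, res$selected,
                              inst$cohort$patient_id)
  expect_equal(unname(colSums(X)), as.numeric(res$selected$n_patients))
  expect_true(all(X %in% c(0, 1)))
})
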