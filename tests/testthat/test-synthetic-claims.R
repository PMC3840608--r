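test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_exposed_target = 1.2), "proportions")
  expect_error(sim_config(confounder_prevalences = c(0.5, 0.5)),
               "length n_confounders")
  expect_error(sim_config(n_confounders = 2,
                          confounder_prevalences = c(0.5, 0.5),
                          confounder_exposure_log_ors = 0,
                          confounder_outcome_log_rrs = c(0, 0)),
               "length n_confounders")
})

test_that("identical seeds give bit-identical cohorts and events", {
  cfg <- sim_config(n_patients = 800L, seed = 7L)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a, b)
  ha <- generate_toy_hierarchies(cfg)
  expect_identical(generate_code_events(a, cfg, ha),
                   generate_code_events(b, cfg, ha))
  d <- generate_cohort(sim_config(n_patients = 800L, seed = 8L))
  expect_false(identical(a$exposed, d$exposed))
})

test_that("null effects and no confounding give a crude RR near 1", {
  cfg <- sim_config(n_patients = 60000L, true_rr = 1,
                    baseline_risk = 0.05,
                    confounder_exposure_log_ors = rep(0, 6),
                    confounder_outcome_log_rrs = rep(0, 6), seed = 11L)
  co <- generate_cohort(cfg)
  cr <- crude_risk_ratio(sum(co$outcome[co$exposed == 1]), sum(co$exposed),
                         sum(co$outcome[co$exposed == 0]),
                         sum(1 - co$exposed))
  # 3 SE on the log scale
  expect_lt(abs(cr$log_rr), 3 * cr$se)
})

test_that("crude RR recovers true_rr at the null of no confounding", {
  cfg <- sim_config(n_patients = 60000L, true_rr = 0.5,
                    baseline_risk = 0.05,
                    confounder_exposure_log_ors = rep(0, 6),
                    confounder_outcome_log_rrs = rep(log(1.5), 6), seed = 12L)
  co <- generate_cohort(cfg)
  cr <- crude_risk_ratio(sum(co$outcome[co$exposed == 1]), sum(co$exposed),
                         sum(co$outcome[co$exposed == 0]),
                         sum(1 - co$exposed))
  expect_lt(abs(cr$log_rr - log(0.5)), 3 * cr$se)
})

test_that("positive confounding biases the crude RR upward from true_rr", {
  up <- vapply(1:5, function(s) {
    co <- generate_cohort(sim_config(n_patients = 10000L, seed = s))
    cr <- crude_risk_ratio(sum(co$outcome[co$exposed == 1]), sum(co$exposed),
                           sum(co$outcome[co$exposed == 0]),
                           sum(1 - co$exposed))
    cr$log_rr - log(0.5)
  }, numeric(1))
  expect_true(all(up > 0))
})

test_that("marginal exposure matches the target within Monte-Carlo error", {
  fracs <- vapply(1:8, function(s)
    mean(generate_cohort(sim_config(n_patients = 18829L, seed = s))$exposed),
    numeric(1))
  p <- 7197 / 18829
  se <- sqrt(p * (1 - p) / 18829)
  # mean exposed count across seeds ~ 7197 within 3 SE of the mean
  expect_lt(abs(mean(fracs) - p), 3 * se / sqrt(8))
})

test_that("an infeasible risk model aborts with a calibration error", {
  cfg <- sim_config(n_patients = 2000L, baseline_risk = 0.6,
                    confounder_outcome_log_rrs = rep(log(3), 6), seed = 1L)
  expect_error(generate_cohort(cfg), "more than 1%")
})

test_that("confounder-free, noise-free configurations emit zero events", {
  cfg <- sim_config(n_patients = 50L, n_confounders = 0L,
                    confounder_prevalences = numeric(),
                    confounder_exposure_log_ors = numeric(),
                    confounder_outcome_log_rrs = numeric(),
                    noise_code_rate = 0, seed = 1L)
  co <- generate_cohort(cfg)
  ev <- generate_code_events(co, cfg)
  expect_identical(nrow(ev), 0L)
})

test_that("sub-threshold split keeps every child code below the screen", {
  cfg <- sim_config(seed = 5L, sub_threshold_split = TRUE)
  co <- generate_cohort(cfg)
  h <- generate_toy_hierarchies(cfg)
  ev <- generate_code_events(co, cfg, h)
  Z <- attr(co, "confounders")
  carriers <- sum(Z[, cfg$n_confounders])
  child_counts <- table(ev$code[ev$code %in% h$split$children])
  expect_true(all(child_counts < cfg$split_max_child_patients))
  expect_identical(sum(child_counts), carriers)   # parent covers all carriers
  # impossible splits abort rather than silently violating the bound
  expect_error(hdpsagg:::split_over_children(600L, letters[1:5], 100L),
               "impossible")
})

test_that("occurrence counts are overdispersed enough for a frequent tier", {
  cfg <- sim_config(n_patients = 4000L, seed = 2L)
  co <- generate_cohort(cfg)
  ev <- generate_code_events(co, cfg)
  expect_true(all(ev$n_occurrences >= 1))
  one_code <- ev[ev$code == ev$code[1], ]
  th <- recurrence_thresholds(one_code$n_occurrences)
  expect_gte(th[["frequent"]], 2)   # some patients qualify beyond "once"
  expect_gt(sum(one_code$n_occurrences >= th[["frequent"]]), 0)
})

test_that("claims tables round-trip losslessly through CSV", {
  cfg <- sim_config(n_patients = 120L, seed = 3L)
  co <- generate_cohort(cfg)
  ev <- generate_code_events(co, cfg)
  dir <- withr::local_tempdir()
  write_claims_tables(co, ev, dir)
  back <- read_claims_tables(dir)
  expect_equal(as.data.frame(back$cohort), as.data.frame(co),
               ignore_attr = TRUE)
  expect_equal(back$events, ev, ignore_attr = TRUE)
})

test_that("malformed claims tables are rejected with row and column", {
  cfg <- sim_config(n_patients = 30L, seed = 4L)
  co <- generate_cohort(cfg)
  ev <- generate_code_events(co, cfg)
  dir <- withr::local_tempdir()
  write_claims_tables(co, ev, dir)

  bad <- ev; bad$n_occurrences[2] <- 0L
  write.csv(bad, file.path(dir, "events.csv"), row.names = FALSE)
  expect_error(read_claims_tables(dir), "row 2, column n_occurrences")

  bad <- ev; bad$dimension[3] <- "telephone"
  write.csv(bad, file.path(dir, "events.csv"), row.names = FALSE)
  expect_error(read_claims_tables(dir), "row 3, column dimension")
})
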