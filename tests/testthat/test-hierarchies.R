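test_that("ATC truncation returns the level prefix", {
  expect_equal(as.character(truncate_atc("B01AC04", 4)), "B01AC")
  expect_equal(as.character(truncate_atc("B01AA03", 5)), "B01AA03")
  expect_equal(as.character(truncate_atc("B01AA03", 1)), "B")
  short <- truncate_atc(c("B01", "B01AC04"), 4)   # too-short code passes through
  expect_equal(as.character(short), c("B01", "B01AC"))
  expect_equal(attr(short, "n_short"), 1L)
  expect_error(truncate_atc("", 3), "empty")
})

test_that("ICD-9 truncation counts significant digits, not the decimal", {
  expect_equal(truncate_icd9("530.11", 4), "530.1")
  expect_equal(truncate_icd9("530.11", 3), "530")
  expect_equal(truncate_icd9("714", 4), "714")
  expect_equal(truncate_icd9("53011", 4), "530.1")   # either dialect
  expect_equal(truncate_icd9("V10.1", 3), "V10")     # prefix part of the stem
})

test_that("the multi-level diagnosis cross-map loads and maps correctly", {
  map <- read_ccs_map(system.file("extdata", "toy_ccs_map.csv",
                                  package = "hdpsagg"))
  expect_s3_class(map, "ccs_map")
  expect_equal(as.character(map_to_ccs("530.11", 1, map)), "9")
  expect_equal(as.character(map_to_ccs("53011", 4, map)), "9.4.1.1")
  # universal = deepest available level
  expect_equal(as.character(map_to_ccs("578.0", "universal", map)), "9.8")
  expect_equal(as.character(map_to_ccs("531.10", "universal", map)), "9.5.1")
  # absent code passes through unchanged and is counted
  out <- map_to_ccs(c("999.9", "714.0"), 1, map)
  expect_equal(as.character(out), c("999.9", "13"))
  expect_equal(attr(out, "n_unmapped"), 1L)
})

test_that("hierarchically inconsistent cross-maps are rejected", {
  bad <- data.frame(icd9_code = "123.4", ccs_level1 = "1", ccs_level2 = "",
                    ccs_level3 = "1.1.1", ccs_level4 = "",
                    stringsAsFactors = FALSE)
  expect_error(read_ccs_map(bad), "level 3 present while level 2 missing")
})

test_that("flat ATC lists load with levels inferred from code width", {
  atc <- read_atc_map(system.file("extdata", "toy_atc.csv",
                                  package = "hdpsagg"))
  expect_equal(atc$level[atc$code == "B"], 1L)
  expect_equal(atc$level[atc$code == "B01AC04"], 5L)
  expect_error(read_atc_map(data.frame(code = "B01AC0", name = "x")),
               "width")
})

test_that("toy hierarchies have consistent tree arithmetic", {
  cfg <- sim_config(hierarchy_branching = list(atc = c(2L, 2L, 2L, 2L, 2L),
                                               dx = c(4L, 2L, 2L)),
                    codes_per_dimension = 4L, n_confounders = 2L,
                    confounder_prevalences = c(0.2, 0.1),
                    confounder_exposure_log_ors = c(0, 0),
                    confounder_outcome_log_rrs = c(0, 0),
                    split_n_children = 2L)
  h <- generate_toy_hierarchies(cfg)
  expect_length(h$atc_leaves, 32L)
  expect_length(unique(substr(h$atc_leaves, 1L, 5L)), 16L)   # level-4 groups
  # the generated cross-map round-trips through the real-file reader
  expect_s3_class(read_ccs_map(h$ccs), "ccs_map")
  # zero missing fraction: universal mapping equals the level-4 mapping
  cfg0 <- sim_config(ccs_missing_fraction = 0)
  h0 <- generate_toy_hierarchies(cfg0)
  m0 <- read_ccs_map(h0$ccs)
  expect_equal(as.character(map_to_ccs(h0$dx_leaves, "universal", m0)),
               as.character(map_to_ccs(h0$dx_leaves, 4, m0)))
})

test_that("aggregation scenarios transform, drop and merge as specified", {
  ev <- tiny_events(c(1L, 1L, 2L), "pharmacy",
                    c("B01AC04", "B01AC05", "B01AA03"), c(1L, 2L, 4L))
  ev <- rbind(ev, tiny_events(1L, "dx_outpatient", "53011", 2L))

  base <- apply_aggregation_scenario(ev, aggregation_scenario())
  expect_equal(base[order(base$patient_id, base$dimension, base$code), ],
               ev[order(ev$patient_id, ev$dimension, ev$code), ],
               ignore_attr = TRUE)

  atc4 <- apply_aggregation_scenario(ev, aggregation_scenario(rx = "atc4"))
  merged <- atc4[atc4$patient_id == 1L & atc4$dimension == "pharmacy", ]
  expect_equal(merged$code, "B01AC")
  expect_equal(merged$n_occurrences, 3L)   # 1 + 2 pooled into the parent

  nodx <- apply_aggregation_scenario(ev, aggregation_scenario(dx = "none"))
  expect_false(any(nodx$dimension %in% c("dx_inpatient", "dx_outpatient")))
  expect_equal(sum(nodx$dimension == "pharmacy"), 3L)

  norx <- apply_aggregation_scenario(ev, aggregation_scenario(rx = "none"))
  expect_false(any(norx$dimension == "pharmacy"))

  expect_error(apply_aggregation_scenario(ev, aggregation_scenario(dx = "ccs1")),
               "cross-map")
})

test_that("aggregation preserves mass, prevalence and idempotence", {
  cfg <- sim_config(n_patients = 500L, seed = 9L)
  co <- generate_cohort(cfg)
  h <- generate_toy_hierarchies(cfg)
  ev <- generate_code_events(co, cfg, h)
  for (sc in list(aggregation_scenario(rx = "atc2"),
                  aggregation_scenario(rx = "atc4", dx = "ccs1"),
                  aggregation_scenario(dx = "icd3"),
                  aggregation_scenario(dx = "ccs_universal"))) {
    agg <- apply_aggregation_scenario(ev, sc, h)
    # occurrence mass conserved within retained dimensions
    expect_equal(sum(agg$n_occurrences), sum(ev$n_occurrences))
    # idempotence
    agg2 <- apply_aggregation_scenario(agg, sc, h)
    expect_equal(agg2, agg, ignore_attr = TRUE)
    # output-code patient count >= max constituent input-code patient count
    pc_in <- tapply(ev$patient_id, ev$code, function(p) length(unique(p)))
    pc_out <- tapply(agg$patient_id, agg$code, function(p) length(unique(p)))
    rx_lvl <- if (sc$rx == "atc2") 2L else if (sc$rx == "atc4") 4L else NULL
    if (!is.null(rx_lvl)) {
      rx_codes <- unique(ev$code[ev$dimension == "pharmacy"])
      parents <- as.character(truncate_atc(rx_codes, rx_lvl))
      for (i in seq_along(rx_codes))
        expect_gte(pc_out[[parents[i]]], pc_in[[rx_codes[i]]])
    }
    # coarser drug levels never increase the number of distinct codes
    expect_lte(length(unique(agg$code[agg$dimension == "pharmacy"])),
               length(unique(ev$code[ev$dimension == "pharmacy"])))
  }
})
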