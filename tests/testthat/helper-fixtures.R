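# Small deterministic fixtures and an independent brute-force implementation
# of the covariate engine, used as an oracle in equivalence tests.

tiny_cohort <- function(n = 40L, exposed = rep(c(1L, 0L), length.out = n),
                        outcome = rep(c(1L, 0L, 0L, 0L), length.out = n)) {
  data.frame(patient_id = seq_len(n),
             age = rep(50L, n), sex = rep(0L, n), index_year = rep(2003L, n),
             exposed = exposed, outcome = outcome,
             stringsAsFactors = FALSE)
}

tiny_events <- function(patient_id, dimension, code, n_occurrences = 1L) {
  if (length(patient_id) == 0L)
    return(data.frame(patient_id = integer(), dimension = character(),
                      code = character(), n_occurrences = integer(),
                      stringsAsFactors = FALSE))
  data.frame(patient_id = as.integer(patient_id),
             dimension = dimension, code = code,
             n_occurrences = as.integer(n_occurrences),
             stringsAsFactors = FALSE)
}

# a random small instance for property-style tests: n patients, a handful of
# codes in up to three dimensions
random_instance <- function(n = 200L, n_codes = 12L, seed = 1L) {
  set.seed(seed)
  dims <- sample(c("pharmacy", "dx_outpatient", "px_inpatient"),
                 n_codes, replace = TRUE)
  codes <- sprintf("C%02d", seq_len(n_codes))
  rows <- list()
  for (j in seq_len(n_codes)) {
    carriers <- sample(n, rbinom(1L, n, runif(1, 0.05, 0.6)))
    if (!length(carriers)) next
    rows[[j]] <- tiny_events(carriers, dims[j], codes[j],
                             sample(1:6, length(carriers), replace = TRUE))
  }
  cohort <- tiny_cohort(n, exposed = rbinom(n, 1L, 0.4),
                        outcome = rbinom(n, 1L, 0.2))
  list(cohort = cohort, events = do.call(rbind, rows))
}

# brute-force covariate engine: plain loops, no shared code with the package
oracle_hdps_selection <- function(events, cohort, n_per_dimension = 200L,
                                  k_select = 500L, min_patients = 0L,
                                  q = 0.75) {
  cand <- list()
  for (d in sort(unique(events$dimension))) {
    evd <- events[events$dimension == d, , drop = FALSE]
    codes <- unique(evd$code)
    cnt <- vapply(codes, function(cd)
      length(unique(evd$patient_id[evd$code == cd])), integer(1))
    top <- codes[order(-cnt, codes)][seq_len(min(n_per_dimension, length(codes)))]
    for (cd in top) {
      rows <- evd[evd$code == cd, , drop = FALSE]
      occ <- tapply(rows$n_occurrences, rows$patient_id, sum)
      pats <- as.integer(names(occ))
      xs <- sort(occ)
      cuts <- c(once = 1,
                sporadic = unname(ceiling(median(occ))),
                frequent = unname(ceiling(xs[max(1L, ceiling(q * length(xs)))])))
      seen <- list()
      for (lev in names(cuts)) {
        set <- sort(pats[occ >= cuts[[lev]]])
        if (any(vapply(seen, identical, logical(1), y = set))) next
        seen[[length(seen) + 1L]] <- set
        ind <- cohort$patient_id %in% set
        n <- sum(ind)
        p1 <- sum(ind & cohort$exposed == 1L) / sum(cohort$exposed == 1L)
        p0 <- sum(ind & cohort$exposed == 0L) / sum(cohort$exposed == 0L)
        rr_cd <- (sum(cohort$outcome[ind]) / n) /
                 (sum(cohort$outcome[!ind]) / sum(!ind))
        cand[[length(cand) + 1L]] <- data.frame(
          dimension = d, code = cd, recurrence_level = lev, n_patients = n,
          p_c1 = p1, p_c0 = p0, rr_ce = p1 / p0, rr_cd = rr_cd,
          stringsAsFactors = FALSE)
      }
    }
  }
  cand <- do.call(rbind, cand)
  ok <- cand$n_patients >= min_patients &
    is.finite(cand$rr_ce) & cand$rr_ce > 0 &
    is.finite(cand$rr_cd) & cand$rr_cd > 0
  cand <- cand[ok, , drop = FALSE]
  r <- pmax(cand$rr_cd, 1 / cand$rr_cd)
  cand$abs_log_bias <- abs(log((cand$p_c1 * (r - 1) + 1) /
                               (cand$p_c0 * (r - 1) + 1)))
  lvr <- match(cand$recurrence_level, c("once", "sporadic", "frequent"))
  ord <- order(-cand$abs_log_bias, cand$dimension, cand$code, lvr)
  out <- cand[ord, , drop = FALSE][seq_len(min(k_select, nrow(cand))), ]
  rownames(out) <- NULL
  out
}

selection_keys <- function(df) {
  paste(df$dimension, df$code, df$recurrence_level, sep = ":")
}

# deterministic event table in which every code has non-degenerate recurrence
# cutoffs (counts 1 / 2 / 5 over its carriers, so once/sporadic/frequent are
# three distinct indicators)
nondegenerate_events <- function(n_codes_per_dim = 210L, n_patients = 600L,
                                 patients_per_code = 120L) {
  dims <- c("pharmacy", "dx_inpatient", "dx_outpatient",
            "px_inpatient", "px_outpatient")
  rows <- vector("list", length(dims) * n_codes_per_dim)
  i <- 0L
  stopifnot(patients_per_code < n_patients)
  # mix chosen so median (2) and 75th percentile (5) cutoffs are distinct,
  # giving three distinct recurrence indicators per code
  counts <- rep(c(1L, 2L, 5L), c(50L, 30L, 40L))[seq_len(patients_per_code)]
  for (d in dims) {
    for (j in seq_len(n_codes_per_dim)) {
      i <- i + 1L
      # 120 consecutive ids (mod n): always distinct, shifted per code
      pats <- ((j * 7L + seq_len(patients_per_code)) %% n_patients) + 1L
      rows[[i]] <- tiny_events(pats, d, sprintf("%s_%03d", d, j), counts)
    }
  }
  do.call(rbind, rows)
}
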