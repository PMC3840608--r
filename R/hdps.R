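#' Configuration of the empirical covariate engine
#'
#' @param n_per_dimension number of most-prevalent codes retained per data
#'   dimension (default 200).
#' @param k_select number of prioritized indicator covariates selected for the
#'   propensity score (default 500).
#' @param min_patients minimum number of patients (exposed and unexposed
#'   combined) a candidate must occur in; 0 disables the screen, emulating the
#'   later algorithm revision that removed the minimum-frequency restriction.
#' @param recurrence_quantile upper quantile defining the "frequent"
#'   recurrence level (default 0.75).
#' @return An object of class \code{hdps_config}. The engine is fully
#'   deterministic - there is no seed.
#' @export
hdps_config <- function(n_per_dimension = 200L, k_select = 500L,
                        min_patients = 100L, recurrence_quantile = 0.75) {
  stopifnot(n_per_dimension >= 1L, k_select >= 1L, min_patients >= 0L,
            recurrence_quantile > 0, recurrence_quantile < 1)
  structure(list(n_per_dimension = as.integer(n_per_dimension),
                 k_select = as.integer(k_select),
                 min_patients = as.integer(min_patients),
                 recurrence_quantile = recurrence_quantile),
            class = "hdps_config")
}

RECURRENCE_LEVELS <- c("once", "sporadic", "frequent")

#' Rank codes of one dimension by patient-level prevalence
#'
#' Prevalence counts distinct patients with at least one occurrence (not
#' claims). Ties are broken by code text ascending, so the ranking is
#' deterministic.
#'
#' @param events event table restricted (or restrictable) to one dimension.
#' @param dimension the dimension to rank.
#' @param n_per_dimension how many top codes to return.
#' @return Character vector of codes, most prevalent first.
#' @export
rank_prevalent_codes <- function(events, dimension, n_per_dimension = 200L) {
  ev <- events[events$dimension == dimension, , drop = FALSE]
  if (nrow(ev) == 0L) return(character())
  counts <- tapply(ev$patient_id, ev$code, function(p) length(unique(p)))
  ord <- order(-counts, names(counts))
  head(names(counts)[ord], n_per_dimension)
}

#' Recurrence cutoffs for one code
#'
#' Computed over the occurrence counts of patients having the code at least
#' once: the sporadic cutoff is the smallest integer at or above the median,
#' the frequent cutoff the smallest integer at or above the nearest-rank
#' quantile (default 75th percentile).
#'
#' @param counts positive occurrence counts, one per patient with the code.
#' @param recurrence_quantile upper quantile for the frequent level.
#' @return Named numeric vector \code{c(sporadic=, frequent=)}.
#' @export
recurrence_thresholds <- function(counts, recurrence_quantile = 0.75) {
  if (length(counts) == 0L) stop("no occurrence counts")
  stopifnot(all(counts >= 1))
  c(sporadic = ceiling(median(counts)),
    frequent = ceiling(nearest_rank_quantile(counts, recurrence_quantile)))
}

#' Expand one code into recurrence-level indicator candidates
#'
#' A patient qualifies for a level when their occurrence count reaches that
#' level's cutoff (once = 1). Because the patient sets are nested, two levels
#' are identical exactly when they have the same size; duplicated indicators
#' are dropped, keeping the least restrictive label, to avoid perfectly
#' collinear covariates.
#'
#' @param code the code.
#' @param dimension its dimension.
#' @param patient_ids patients having the code.
#' @param counts their occurrence counts.
#' @param thresholds from [recurrence_thresholds()].
#' @return A list of candidate covariates, each a list with \code{dimension,
#'   code, recurrence_level, count_threshold, patients}.
#' @export
expand_recurrence_indicators <- function(code, dimension, patient_ids, counts,
                                         thresholds) {
  cuts <- c(once = 1, sporadic = unname(thresholds["sporadic"]),
            frequent = unname(thresholds["frequent"]))
  out <- list()
  prev_size <- -1L
  for (lev in RECURRENCE_LEVELS) {
    keep <- patient_ids[counts >= cuts[lev]]
    if (length(keep) == prev_size) next      # identical nested set: duplicate
    prev_size <- length(keep)
    out[[length(out) + 1L]] <- list(dimension = dimension, code = code,
                                    recurrence_level = lev,
                                    count_threshold = cuts[[lev]],
                                    patients = keep)
  }
  out
}

#' Prevalences and bivariate associations of a candidate covariate
#'
#' @param in_covariate logical/0-1 vector over all patients (covariate
#'   indicator).
#' @param exposed,outcome 0/1 vectors over the same patients.
#' @return A list with \code{p_c1} (prevalence in exposed), \code{p_c0}
#'   (prevalence in unexposed), \code{prevalence} (overall), \code{rr_ce}
#'   (covariate-exposure prevalence ratio) and \code{rr_cd} (risk of outcome
#'   in covariate-positive over covariate-negative patients). Zero cells give
#'   0, \code{Inf} or \code{NaN}, which the screen removes.
#' @export
covariate_associations <- function(in_covariate, exposed, outcome) {
  cov <- as.logical(in_covariate)
  n1 <- sum(exposed == 1L); n0 <- sum(exposed == 0L)
  p_c1 <- sum(cov & exposed == 1L) / n1
  p_c0 <- sum(cov & exposed == 0L) / n0
  risk_in <- sum(outcome[cov]) / sum(cov)
  risk_out <- sum(outcome[!cov]) / sum(!cov)
  list(p_c1 = p_c1, p_c0 = p_c0, prevalence = mean(cov),
       rr_ce = p_c1 / p_c0, rr_cd = risk_in / risk_out)
}

#' Bross bias multiplier of a binary covariate
#'
#' The factor by which an unadjusted binary covariate with prevalence
#' \code{p_c1} in the exposed, \code{p_c0} in the unexposed and outcome risk
#' ratio \code{rr_cd} could bias an exposure-outcome risk ratio:
#' \deqn{B = \frac{p_{c1}(r-1)+1}{p_{c0}(r-1)+1}, \quad
#'       r = \max(rr_{cd}, 1/rr_{cd})}
#' The apparent relative risk is forced to at least 1 so protective and
#' harmful covariate-outcome associations prioritize alike; the prioritization
#' key is \eqn{|\ln B|}.
#'
#' @param p_c1,p_c0 prevalences in exposed / unexposed, in \[0, 1\].
#' @param rr_cd covariate-outcome risk ratio, > 0.
#' @return The bias multiplier (vectorized).
#' @export
bross_bias_multiplier <- function(p_c1, p_c0, rr_cd) {
  if (any(p_c1 < 0 | p_c1 > 1 | p_c0 < 0 | p_c0 > 1))
    stop("prevalences must lie in [0, 1]")
  if (any(!is.finite(rr_cd) | rr_cd <= 0))
    stop("rr_cd must be finite and positive (screen candidates first)")
  r <- pmax(rr_cd, 1 / rr_cd)
  (p_c1 * (r - 1) + 1) / (p_c0 * (r - 1) + 1)
}

#' Screen candidate covariates
#'
#' Drops candidates occurring in fewer than \code{min_patients} patients
#' (boundary inclusive: exactly \code{min_patients} is retained) and
#' candidates whose covariate-exposure or covariate-outcome ratio is zero,
#' infinite or undefined (any structural zero cell). Drop counts by reason are
#' attached as attribute \code{"screen_counts"}.
#'
#' @param candidates data.frame with columns \code{n_patients, rr_ce, rr_cd}.
#' @param min_patients the minimum-frequency screen.
#' @return The surviving rows.
#' @export
screen_candidates <- function(candidates, min_patients = 100L) {
  too_few <- candidates$n_patients < min_patients
  bad_ce <- !is.finite(candidates$rr_ce) | candidates$rr_ce <= 0
  bad_cd <- !is.finite(candidates$rr_cd) | candidates$rr_cd <= 0
  keep <- !(too_few | bad_ce | bad_cd)
  out <- candidates[keep, , drop = FALSE]
  attr(out, "screen_counts") <- c(below_min_patients = sum(too_few),
                                  undefined_exposure_ratio = sum(bad_ce & !too_few),
                                  undefined_outcome_ratio = sum(bad_cd & !too_few & !bad_ce))
  out
}

#' Select the top-k covariates by confounding potential
#'
#' Sorts by \eqn{|\ln B|} descending; ties are broken by (dimension, code,
#' recurrence level) ascending, with recurrence levels ordered once <
#' sporadic < frequent, so selection is deterministic.
#'
#' @param prioritized data.frame with columns \code{abs_log_bias, dimension,
#'   code, recurrence_level}.
#' @param k_select number to keep.
#' @return The selected rows with a \code{rank} column.
#' @export
select_top_covariates <- function(prioritized, k_select = 500L) {
  lev <- match(prioritized$recurrence_level, RECURRENCE_LEVELS)
  ord <- order(-prioritized$abs_log_bias, prioritized$dimension,
               prioritized$code, lev)
  out <- prioritized[head(ord, k_select), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full empirical covariate engine
#'
#' Identify (top-\code{n_per_dimension} most prevalent codes per dimension),
#' expand (once/sporadic/frequent recurrence indicators), screen (minimum
#' patient count; defined, non-zero bivariate associations), prioritize (Bross
#' bias multiplier) and select (top \code{k_select} by \eqn{|\ln B|}).
#'
#' @param events event table (post-aggregation).
#' @param cohort cohort data.frame supplying \code{patient_id, exposed,
#'   outcome}.
#' @param config an [hdps_config()].
#' @return A list of class \code{hdps_result}: \code{selected} (data.frame
#'   with dimension, code, recurrence_level, count_threshold, n_patients,
#'   p_c1, p_c0, rr_ce, rr_cd, bias_multiplier, abs_log_bias, rank),
#'   \code{candidates} (all pre-screen candidates with their statistics),
#'   \code{screen_counts}, and \code{n_candidates}.
#' @export
hdps_covariates <- function(events, cohort, config = hdps_config()) {
  stopifnot(inherits(config, "hdps_config"))
  n_occurrences <- patient_id <- code <- NULL  # data.table NSE
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    empty <- empty_candidate_frame()
    return(structure(list(selected = empty, candidates = empty,
                          screen_counts = c(below_min_patients = 0L,
                                            undefined_exposure_ratio = 0L,
                                            undefined_outcome_ratio = 0L),
                          n_candidates = 0L),
                     class = "hdps_result"))
  }
  ev <- ev[, list(n_occurrences = sum(n_occurrences)),
           by = c("patient_id", "dimension", "code")]

  # top-n most prevalent codes per dimension (tie-break: code ascending)
  pc <- ev[, list(n_patients = .N), by = c("dimension", "code")]
  data.table::setorderv(pc, c("dimension", "n_patients", "code"),
                        order = c(1L, -1L, 1L))
  top <- pc[, head(.SD, config$n_per_dimension), by = "dimension"]
  ev <- ev[top[, c("dimension", "code")], on = c("dimension", "code")]

  # per-code recurrence cutoffs and nested-set sizes/statistics
  expo <- cohort$exposed[match(ev$patient_id, cohort$patient_id)]
  outc <- cohort$outcome[match(ev$patient_id, cohort$patient_id)]
  ev[, `:=`(.expo = expo, .outc = outc)]
  q <- config$recurrence_quantile
  per_code <- ev[, {
    s <- ceiling(median(n_occurrences))
    f <- ceiling(nearest_rank_quantile(n_occurrences, q))
    cuts <- c(1, s, f)
    ns <- integer(3L); es <- integer(3L); cs <- integer(3L)
    for (i in 1:3) {
      sel <- n_occurrences >= cuts[i]
      ns[i] <- sum(sel); es[i] <- sum(.expo[sel]); cs[i] <- sum(.outc[sel])
    }
    list(recurrence_level = RECURRENCE_LEVELS, count_threshold = cuts,
         n_patients = ns, n_exposed = es, n_cases = cs)
  }, by = c("dimension", "code")]

  # nested sets are equal iff equal in size; keep the least restrictive label
  per_code[, dup := duplicated(n_patients), by = c("dimension", "code")]
  cand <- per_code[dup == FALSE][, dup := NULL]

  N1 <- sum(cohort$exposed == 1L); N0 <- sum(cohort$exposed == 0L)
  C <- sum(cohort$outcome); N <- nrow(cohort)
  cand[, `:=`(
    p_c1 = n_exposed / N1,
    p_c0 = (n_patients - n_exposed) / N0,
    prevalence = n_patients / N
  )]
  cand[, rr_ce := p_c1 / p_c0]
  cand[, rr_cd := (n_cases / n_patients) / ((C - n_cases) / (N - n_patients))]
  data.table::setDF(cand)

  screened <- screen_candidates(cand, config$min_patients)
  counts <- attr(screened, "screen_counts")
  if (nrow(screened)) {
    screened$bias_multiplier <- bross_bias_multiplier(screened$p_c1,
                                                      screened$p_c0,
                                                      screened$rr_cd)
    screened$abs_log_bias <- abs(log(screened$bias_multiplier))
  } else {
    screened$bias_multiplier <- numeric(); screened$abs_log_bias <- numeric()
  }
  selected <- select_top_covariates(screened, config$k_select)
  structure(list(selected = selected, candidates = cand,
                 screen_counts = counts, n_candidates = nrow(cand)),
            class = "hdps_result")
}

empty_candidate_frame <- function() {
  data.frame(dimension = character(), code = character(),
             recurrence_level = character(), count_threshold = numeric(),
             n_patients = integer(), n_exposed = integer(),
             n_cases = integer(), p_c1 = numeric(), p_c0 = numeric(),
             prevalence = numeric(), rr_ce = numeric(), rr_cd = numeric(),
             stringsAsFactors = FALSE)
}

#' Build the patient-by-covariate indicator matrix for selected covariates
#'
#' @param events the (post-aggregation) event table used for selection.
#' @param selected the \code{selected} data.frame of an [hdps_covariates()]
#'   result.
#' @param patient_ids patient identifiers defining the row order.
#' @return A 0/1 matrix with one column per selected covariate, named
#'   \code{dimension:code:recurrence_level}.
#' @export
build_indicator_matrix <- function(events, selected, patient_ids) {
  n_occurrences <- NULL
  X <- matrix(0, nrow = length(patient_ids), ncol = nrow(selected))
  if (nrow(selected) == 0L) return(X)
  colnames(X) <- paste(selected$dimension, selected$code,
                       selected$recurrence_level, sep = ":")
  ev <- data.table::as.data.table(events)
  ev <- ev[, list(n_occurrences = sum(n_occurrences)),
           by = c("patient_id", "dimension", "code")]
  sel <- data.table::as.data.table(
    selected[c("dimension", "code", "count_threshold")])
  sel[, .col := seq_len(.N)]
  hit <- ev[sel, on = c("dimension", "code"), allow.cartesian = TRUE,
            nomatch = NULL]
  hit <- hit[n_occurrences >= count_threshold]
  row <- match(hit$patient_id, patient_ids)
  ok <- !is.na(row)
  X[cbind(row[ok], hit$.col[ok])] <- 1
  X
}

#' Covariate report in the shape of a selected-covariate table
#'
#' @param result an [hdps_covariates()] result.
#' @param file optional CSV path to write.
#' @return The report data.frame (dimension, code, recurrence_level, p_c1,
#'   p_c0, rr_ce, rr_cd, bias_multiplier, rank), invisibly when written.
#' @export
hdps_covariate_report <- function(result, file = NULL) {
  stopifnot(inherits(result, "hdps_result"))
  rep <- result$selected[c("dimension", "code", "recurrence_level", "p_c1",
                           "p_c0", "rr_ce", "rr_cd", "bias_multiplier",
                           "rank")]
  if (!is.null(file)) {
    write.csv(rep, file, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
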