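#' Generate a synthetic claims cohort
#'
#' Draws latent binary confounders, then exposure from a logistic model in the
#' confounders (intercept solved numerically so the cohort-average exposure
#' probability equals \code{p_exposed_target}), then the binary 60-day outcome
#' from a log-link risk model
#' \deqn{risk = baseline\_risk \times true\_rr^{exposed} \times
#'       \exp(\sum_j \gamma_j Z_j)}
#' so \code{true_rr} is a marginal risk ratio. Age, sex and index year are
#' generated independently of the confounders unless
#' \code{age_exposure_link} is set. The pre-selected "extended" covariate
#' flags are noisy measurements of the confounders.
#'
#' @param config a [sim_config()].
#' @return A \code{data.frame} of class \code{claims_cohort} with columns
#'   \code{patient_id, age, sex, index_year, exposed, outcome} and one
#'   \code{ext_*} column per extended flag. The latent confounder matrix is
#'   attached as attribute \code{"confounders"} and the configuration as
#'   attribute \code{"config"}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  k <- config$n_confounders
  with_local_seed(config$seed, {
    Z <- matrix(0L, nrow = n, ncol = k)
    if (k > 0) {
      for (j in seq_len(k))
        Z[, j] <- rbinom(n, 1L, config$confounder_prevalences[j])
      colnames(Z) <- paste0("Z", seq_len(k))
    }

    age <- pmin(65, pmax(18, round(rnorm(n, 52, 9.5))))
    sex <- rbinom(n, 1L, 0.60)            # 1 = female
    index_year <- 2003L + rbinom(n, 1L, 0.45)

    lp <- if (k > 0) drop(Z %*% config$confounder_exposure_log_ors) else rep(0, n)
    if (config$age_exposure_link) lp <- lp + 0.03 * (age - 52)
    alpha <- uniroot(function(a) mean(plogis(a + lp)) - config$p_exposed_target,
                     interval = c(-30, 30), tol = 1e-10)$root
    exposed <- rbinom(n, 1L, plogis(alpha + lp))

    log_risk <- log(config$baseline_risk) + exposed * log(config$true_rr) +
      (if (k > 0) drop(Z %*% config$confounder_outcome_log_rrs) else 0)
    risk <- exp(log_risk)
    clipped <- risk >= 1
    if (mean(clipped) > 0.01)
      stop("risk model yields risk >= 1 for more than 1% of patients; ",
           "re-calibrate baseline_risk / confounder_outcome_log_rrs")
    if (any(clipped)) {
      warning(sum(clipped), " patient risk(s) clipped below 1")
      risk[clipped] <- 1 - 1e-12
    }
    outcome <- rbinom(n, 1L, risk)

    cohort <- data.frame(patient_id = seq_len(n), age = age, sex = sex,
                         index_year = index_year, exposed = exposed,
                         outcome = outcome, stringsAsFactors = FALSE)

    flag_names <- c("hypertension", "gastroprotective_use",
                    "coronary_artery_disease", "oral_steroid_use",
                    "warfarin_use", "antiplatelet_use",
                    "congestive_heart_failure", "inflammatory_bowel_disease")
    for (j in seq_len(min(k, length(flag_names)))) {
      obs <- ifelse(Z[, j] == 1L,
                    rbinom(n, 1L, config$ext_flag_sensitivity),
                    rbinom(n, 1L, config$ext_flag_fpr))
      cohort[[paste0("ext_", flag_names[j])]] <- obs
    }

    attr(cohort, "confounders") <- Z
    attr(cohort, "config") <- config
    attr(cohort, "exposure_intercept") <- alpha
    class(cohort) <- c("claims_cohort", "data.frame")
    cohort
  })
}

#' Names of the extended-covariate flag columns of a cohort
#' @param cohort a cohort data.frame.
#' @return Character vector of column names beginning with \code{ext_}.
#' @export
extended_flag_columns <- function(cohort) {
  grep("^ext_", names(cohort), value = TRUE)
}

#' Generate baseline code events for a cohort
#'
#' Every latent confounder emits its proxy code (in its assigned dimension)
#' for each patient carrying it, with a zero-truncated geometric occurrence
#' count, so downstream covariate screening can rediscover the confounders
#' from claims alone. When \code{sub_threshold_split} is on, the designated
#' confounder's carriers are spread over sibling child codes such that every
#' child occurs in fewer than \code{split_max_child_patients} patients while
#' the common parent code covers all carriers. Spurious noise events are added
#' at \code{noise_code_rate} per patient, uniformly over dimensions and their
#' background code pools.
#'
#' @param cohort a cohort from [generate_cohort()] (its latent confounder
#'   matrix must still be attached).
#' @param config the [sim_config()] used to generate the cohort.
#' @param hierarchies optional [generate_toy_hierarchies()] result; built from
#'   \code{config} when missing.
#' @return A \code{data.frame} with columns \code{patient_id, dimension, code,
#'   n_occurrences}, one row per (patient, dimension, code).
#' @export
generate_code_events <- function(cohort, config, hierarchies = NULL) {
  stopifnot(inherits(config, "sim_config"))
  Z <- attr(cohort, "confounders")
  if (is.null(Z))
    stop("cohort has no latent confounder matrix; ",
         "generate_code_events() needs a cohort from generate_cohort()")
  if (is.null(hierarchies)) hierarchies <- generate_toy_hierarchies(config)
  stopifnot(inherits(hierarchies, "toy_hierarchies"))
  n <- nrow(cohort)
  p <- config$occurrence_geom_prob

  with_local_seed(child_seed(config$seed, 1L), {
    parts <- list()
    for (j in seq_len(config$n_confounders)) {
      carriers <- cohort$patient_id[Z[, j] == 1L]
      if (length(carriers) == 0L) next
      pr <- hierarchies$proxy[j, ]
      if (config$sub_threshold_split && j == hierarchies$split$confounder) {
        codes <- split_over_children(length(carriers),
                                     hierarchies$split$children,
                                     config$split_max_child_patients)
      } else {
        codes <- rep(pr$code, length(carriers))
      }
      parts[[length(parts) + 1L]] <-
        data.frame(patient_id = carriers, dimension = pr$dimension,
                   code = codes, n_occurrences = rztgeom(length(carriers), p),
                   stringsAsFactors = FALSE)
    }

    if (config$noise_code_rate > 0) {
      n_noise <- rpois(n, config$noise_code_rate)
      total <- sum(n_noise)
      if (total > 0) {
        pid <- rep(cohort$patient_id, n_noise)
        dim_i <- sample(CLAIMS_DIMENSIONS, total, replace = TRUE)
        code <- character(total)
        for (d in CLAIMS_DIMENSIONS) {
          idx <- which(dim_i == d)
          if (length(idx))
            code[idx] <- sample(hierarchies$pools[[d]], length(idx), replace = TRUE)
        }
        parts[[length(parts) + 1L]] <-
          data.frame(patient_id = pid, dimension = dim_i, code = code,
                     n_occurrences = rztgeom(total, p),
                     stringsAsFactors = FALSE)
      }
    }

    if (length(parts) == 0L)
      return(data.frame(patient_id = integer(), dimension = character(),
                        code = character(), n_occurrences = integer(),
                        stringsAsFactors = FALSE))
    ev <- data.table::rbindlist(parts)
    ev <- ev[, list(n_occurrences = sum(n_occurrences)),
             by = c("patient_id", "dimension", "code")]
    data.table::setorder(ev, patient_id, dimension, code)
    data.table::setDF(ev)
    ev
  })
}

# distribute carriers over sibling child codes with every cell strictly below
# `max_child`; rebalancing from the largest to the smallest cell guarantees the
# bound whenever n_carriers < n_children * max_child
split_over_children <- function(n_carriers, children, max_child) {
  if (n_carriers >= length(children) * max_child)
    stop("sub-threshold split impossible: ", n_carriers, " carriers cannot be ",
         "spread over ", length(children), " children each below ", max_child)
  assign <- sample(length(children), n_carriers, replace = TRUE)
  tab <- tabulate(assign, nbins = length(children))
  while (max(tab) >= max_child) {
    from <- which.max(tab)
    to <- which.min(tab)
    move <- which(assign == from)[1L]
    assign[move] <- to
    tab[from] <- tab[from] - 1L
    tab[to] <- tab[to] + 1L
  }
  children[assign]
}
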