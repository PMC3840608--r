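#' Geometric mean and quartiles of replicate risk ratios
#'
#' Non-finite or non-positive estimates are excluded and counted. Percentiles
#' use linear interpolation on the raw risk ratios.
#'
#' @param rrs numeric vector of replicate risk ratios.
#' @return A list with \code{geometric_mean, p25, p75, n_used, n_excluded}.
#' @export
geometric_mean_rr <- function(rrs) {
  ok <- is.finite(rrs) & rrs > 0
  if (!any(ok)) stop("no finite positive risk ratios to summarise")
  x <- rrs[ok]
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  list(geometric_mean = exp(mean(log(x))), p25 = q[1], p75 = q[2],
       n_used = sum(ok), n_excluded = sum(!ok))
}

covariate_keys <- function(selected) {
  if (is.null(selected) || nrow(selected) == 0L) return(character())
  paste(selected$dimension, selected$code, selected$recurrence_level,
        sep = ":")
}

#' Percentage of full-cohort selected covariates recovered in a sample
#'
#' Covariates are identified by (dimension, code, recurrence level).
#'
#' @param full_selection selected-covariate data.frame (or key vector) from
#'   the full cohort.
#' @param sample_selection same, from a sample.
#' @return Percentage in \[0, 100\]; \code{NA} (with a warning) when the
#'   full-cohort selection is empty.
#' @export
variable_coverage <- function(full_selection, sample_selection) {
  fk <- if (is.character(full_selection)) full_selection
        else covariate_keys(full_selection)
  sk <- if (is.character(sample_selection)) sample_selection
        else covariate_keys(sample_selection)
  if (length(fk) == 0L) {
    warning("empty full-cohort selection; coverage undefined")
    return(NA_real_)
  }
  100 * length(intersect(fk, sk)) / length(fk)
}

#' Residual confounding of an estimate against a presumed true risk ratio
#'
#' \eqn{|\ln(RR) - \ln(RR_t)|}: the absolute log-scale distance between the
#' estimate and the presumed unconfounded value (default 0.50, the pooled
#' trial finding the example is anchored to).
#'
#' @param rr estimated risk ratio (> 0).
#' @param rr_t presumed unconfounded risk ratio (> 0).
#' @return Nonnegative numeric (vectorized).
#' @examples
#' residual_confounding(0.89, 0.50)  # 0.577
#' residual_confounding(0.81, 0.50)  # 0.482
#' @export
residual_confounding <- function(rr, rr_t = 0.50) {
  if (any(!is.finite(rr) | rr <= 0) || any(!is.finite(rr_t) | rr_t <= 0))
    stop("risk ratios must be finite and positive")
  abs(log(rr) - log(rr_t))
}

#' Proportional difference in residual confounding versus the base scenario
#'
#' \code{100 * (confounding(rr_scenario) - confounding(rr_base)) /
#' confounding(rr_base)}; negative values mean the scenario is less confounded
#' than the base. Undefined (NA with a warning) when the base estimate shows
#' zero confounding.
#'
#' @param rr_scenario risk ratio under the scenario of interest.
#' @param rr_base risk ratio under the base (no aggregation) scenario.
#' @param rr_t presumed unconfounded risk ratio.
#' @return Signed percentage.
#' @examples
#' proportional_confounding_difference(0.81, 0.89, 0.50)  # about -16.3
#' @export
proportional_confounding_difference <- function(rr_scenario, rr_base,
                                                rr_t = 0.50) {
  base <- residual_confounding(rr_base, rr_t)
  if (any(base == 0)) {
    warning("zero confounding in the base estimate; ",
            "proportional difference undefined")
    return(ifelse(base == 0, NA_real_,
                  100 * (residual_confounding(rr_scenario, rr_t) - base) / base))
  }
  100 * (residual_confounding(rr_scenario, rr_t) - base) / base
}

#' Run the full condition-by-scenario experiment grid
#'
#' For every condition replicate (drawn once and shared across scenarios) and
#' every aggregation scenario: apply the scenario, run the model suite,
#' collect the risk ratios, the variable coverage against the full-cohort
#' selection for that scenario, and the sample margins. Then summarise per
#' (condition, scenario, model) - geometric mean and quartiles of the risk
#' ratios, medians of the margins, mean coverage, fallback and exclusion
#' counts - and compute the confounding metrics of every scenario against the
#' base scenario from the unrounded geometric means.
#'
#' Replicate-level failures are recorded in \code{$errors} and never abort the
#' grid.
#'
#' @param cohort,events full cohort and events.
#' @param scenarios named list of [aggregation_scenario()]s; must contain the
#'   base scenario (rx generic, dx icd5) for the confounding metrics.
#' @param conditions list of [condition_spec()]s.
#' @param maps hierarchy maps passed to [apply_aggregation_scenario()].
#' @param hdps an [hdps_config()].
#' @param models model subset passed to [run_model_suite()].
#' @param rr_t presumed unconfounded risk ratio (default 0.50); all metrics
#'   derive from it.
#' @param out_dir optional directory: writes \code{replicates.csv},
#'   \code{summary.csv}, \code{metrics.csv}, \code{full_cohort.csv} and
#'   \code{run_log.csv}.
#' @param verbose print progress.
#' @return A list of class \code{hdps_experiment}: \code{replicates} (one row
#'   per condition x replicate x scenario x model), \code{summary},
#'   \code{metrics}, \code{full_cohort}, \code{errors}.
#' @export
run_experiment <- function(cohort, events, scenarios, conditions,
                           maps = NULL, hdps = hdps_config(),
                           models = MODEL_NAMES, rr_t = 0.50,
                           out_dir = NULL, verbose = FALSE) {
  stopifnot(length(scenarios) > 0, length(conditions) > 0)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be a named list")
  base_name <- names(scenarios)[vapply(scenarios, is_base_scenario, logical(1))]

  # full-cohort reference run per scenario (selection reused for coverage)
  full_rows <- list(); full_keys <- list()
  for (sn in names(scenarios)) {
    fs <- run_model_suite(cohort, events, scenarios[[sn]], maps, hdps, models)
    full_keys[[sn]] <- covariate_keys(fs$selected)
    full_rows[[sn]] <- cbind(scenario = sn, fs$estimates,
                             stringsAsFactors = FALSE)
  }
  full_cohort <- do.call(rbind, full_rows)
  rownames(full_cohort) <- NULL

  rep_rows <- list(); err_rows <- list()
  for (cond in conditions) {
    cid <- cond$condition_id
    for (r in seq_len(cond$n_replicates)) {
      smp <- draw_condition_sample(cohort, events, cond, r)
      for (sn in names(scenarios)) {
        res <- tryCatch(
          run_model_suite(smp$cohort, smp$events, scenarios[[sn]], maps,
                          hdps, models),
          error = function(e) e)
        if (inherits(res, "error")) {
          err_rows[[length(err_rows) + 1L]] <- data.frame(
            condition_id = cid, replicate = r, scenario = sn,
            message = conditionMessage(res), stringsAsFactors = FALSE)
          next
        }
        cov <- if (is.null(res$selected)) NA_real_
               else variable_coverage(full_keys[[sn]], res$selected)
        est <- res$estimates
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          condition_id = cid, replicate = r, scenario = sn,
          model = est$model, rr = est$rr, ci_lower = est$ci_lower,
          ci_upper = est$ci_upper, fallback_used = est$fallback_used,
          n = nrow(smp$cohort), n_exposed = sum(smp$cohort$exposed),
          n_unexposed = sum(1L - smp$cohort$exposed),
          exposed_cases = sum(smp$cohort$outcome[smp$cohort$exposed == 1L]),
          unexposed_cases = sum(smp$cohort$outcome[smp$cohort$exposed == 0L]),
          coverage = cov, seed = smp$seed, stringsAsFactors = FALSE)
      }
      if (verbose && r %% 10L == 0L)
        message("condition ", cid, ": replicate ", r, "/", cond$n_replicates)
    }
  }
  replicates <- if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else NULL
  if (is.null(replicates)) stop("every replicate failed; see errors")

  summary <- summarize_replicates(replicates)
  metrics <- confounding_metrics(summary, base_name, rr_t)

  out <- structure(list(replicates = replicates, summary = summary,
                        metrics = metrics, full_cohort = full_cohort,
                        errors = errors, rr_t = rr_t),
                   class = "hdps_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(replicates, file.path(out_dir, "replicates.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(full_cohort, file.path(out_dir, "full_cohort.csv"), row.names = FALSE)
    if (!is.null(errors))
      write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  }
  out
}

# per (condition, scenario, model) summary in the shape of the condition table
summarize_replicates <- function(replicates) {
  rr <- coverage <- n_exposed <- n_unexposed <- exposed_cases <-
    unexposed_cases <- fallback_used <- NULL
  dt <- data.table::as.data.table(replicates)
  out <- dt[, {
    gm <- geometric_mean_rr(rr)
    list(geometric_mean_rr = gm$geometric_mean, rr_p25 = gm$p25,
         rr_p75 = gm$p75, n_used = gm$n_used, n_excluded = gm$n_excluded,
         median_n_exposed = median(n_exposed),
         median_n_unexposed = median(n_unexposed),
         median_exposed_cases = median(exposed_cases),
         median_unexposed_cases = median(unexposed_cases),
         pct_exposed = 100 * median(n_exposed) /
           (median(n_exposed) + median(n_unexposed)),
         mean_coverage = if (all(is.na(coverage))) NA_real_
                         else mean(coverage, na.rm = TRUE),
         n_fallback = sum(fallback_used))
  }, by = c("condition_id", "scenario", "model")]
  data.table::setDF(dt <- out)
  dt
}

# proportional confounding difference of every scenario against the base,
# computed from unrounded geometric means
confounding_metrics <- function(summary, base_name, rr_t) {
  if (length(base_name) != 1L) return(NULL)
  base <- summary[summary$scenario == base_name,
                  c("condition_id", "model", "geometric_mean_rr")]
  names(base)[3L] <- "rr_base"
  m <- merge(summary[c("condition_id", "scenario", "model",
                       "geometric_mean_rr")],
             base, by = c("condition_id", "model"))
  names(m)[names(m) == "geometric_mean_rr"] <- "rr_scenario"
  m$rr_t <- rr_t
  m$confounding_base <- residual_confounding(m$rr_base, rr_t)
  m$confounding_scenario <- residual_confounding(m$rr_scenario, rr_t)
  m$proportional_difference <- ifelse(
    m$confounding_base > 0,
    100 * (m$confounding_scenario - m$confounding_base) / m$confounding_base,
    NA_real_)
  m[order(m$condition_id, m$scenario, m$model), ]
}
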