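#' Configuration for the synthetic claims-cohort generator
#'
#' Defines one simulated new-user cohort with confounding by indication: latent
#' binary confounders raise both the probability of receiving the study drug
#' and the risk of the outcome, so the crude risk ratio is biased away from the
#' true one. Defaults emulate the structure of a celecoxib-vs-tNSAID style
#' cohort: 18,829 patients, 38% exposed, a rare (~0.6%) 60-day binary outcome,
#' a true risk ratio of 0.50, and net upward confounding of roughly a factor of
#' two so the crude estimate lands near 1.
#'
#' @param n_patients number of cohort members.
#' @param p_exposed_target target marginal exposure prevalence; the intercept of
#'   the logistic exposure model is solved numerically so the cohort-average
#'   exposure probability equals this value.
#' @param true_rr true marginal risk ratio of exposure on outcome (log link, no
#'   effect modification), default 0.50.
#' @param baseline_risk outcome risk for an unexposed patient with no
#'   confounders.
#' @param n_confounders number of latent binary confounders.
#' @param confounder_prevalences prevalence of each confounder.
#' @param confounder_exposure_log_ors log odds ratios of each confounder on
#'   exposure (logistic exposure model).
#' @param confounder_outcome_log_rrs log risk ratios of each confounder on the
#'   outcome (log-link risk model).
#' @param codes_per_dimension number of "background" codes per claims dimension
#'   available to the noise process (the code universe, scaled down from the
#'   thousands of codes in a real claims database).
#' @param hierarchy_branching list with elements \code{atc} (children per level
#'   of the 5-level toy drug hierarchy) and \code{dx} (children per level of the
#'   toy 3-digit-stem / 4th-digit / 5th-digit diagnosis tree).
#' @param ccs_missing_fraction fraction of diagnosis leaf codes lacking the
#'   deepest grouping level(s) in the toy multi-level diagnosis cross-map
#'   (half of those also lack level 3), emulating incomplete CCS coverage.
#' @param sub_threshold_split logical; when \code{TRUE}, the designated (last)
#'   confounder's pharmacy signal is distributed over sibling child codes so
#'   that every child occurs in fewer patients than a minimum-frequency screen
#'   while their common level-4 parent exceeds it.
#' @param split_n_children number of sibling child codes for the split.
#' @param split_max_child_patients strict upper bound on patients per child
#'   code, enforced by construction (default 100, the classic hd-PS screen).
#' @param occurrence_geom_prob success probability of the zero-truncated
#'   geometric distribution of within-patient occurrence counts.
#' @param noise_code_rate mean number of spurious (confounder-independent) code
#'   events per patient, spread uniformly over dimensions and their code pools.
#' @param ext_flag_sensitivity,ext_flag_fpr sensitivity and false-positive rate
#'   with which the pre-selected "extended" covariate flags measure their
#'   underlying confounders.
#' @param age_exposure_link logical; when \code{TRUE}, age enters the exposure
#'   model (0.03 log odds per year above 52) so the basic-covariate adjustment
#'   has something to do.
#' @param seed integer seed; identical configurations generate bit-identical
#'   cohorts.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_patients = 18829L,
                       p_exposed_target = 7197 / 18829,
                       true_rr = 0.50,
                       baseline_risk = 0.0039,
                       n_confounders = 6L,
                       confounder_prevalences = c(0.22, 0.20, 0.03, 0.12, 0.017, 0.0138),
                       confounder_exposure_log_ors = c(1.0, 1.1, 1.5, 1.1, 1.85, 1.85),
                       confounder_outcome_log_rrs = log(c(2.1, 2.6, 3.8, 2.6, 4.2, 5.2)),
                       codes_per_dimension = 12L,
                       hierarchy_branching = list(atc = c(2L, 3L, 2L, 3L, 5L),
                                                  dx = c(8L, 3L, 3L)),
                       ccs_missing_fraction = 0.15,
                       sub_threshold_split = FALSE,
                       split_n_children = 5L,
                       split_max_child_patients = 100L,
                       occurrence_geom_prob = 0.55,
                       noise_code_rate = 6,
                       ext_flag_sensitivity = 0.9,
                       ext_flag_fpr = 0.02,
                       age_exposure_link = FALSE,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              p_exposed_target = p_exposed_target,
              true_rr = true_rr,
              baseline_risk = baseline_risk,
              n_confounders = as.integer(n_confounders),
              confounder_prevalences = confounder_prevalences,
              confounder_exposure_log_ors = confounder_exposure_log_ors,
              confounder_outcome_log_rrs = confounder_outcome_log_rrs,
              codes_per_dimension = as.integer(codes_per_dimension),
              hierarchy_branching = hierarchy_branching,
              ccs_missing_fraction = ccs_missing_fraction,
              sub_threshold_split = isTRUE(sub_threshold_split),
              split_n_children = as.integer(split_n_children),
              split_max_child_patients = as.integer(split_max_child_patients),
              occurrence_geom_prob = occurrence_geom_prob,
              noise_code_rate = noise_code_rate,
              ext_flag_sensitivity = ext_flag_sensitivity,
              ext_flag_fpr = ext_flag_fpr,
              age_exposure_link = isTRUE(age_exposure_link),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L,
            cfg$true_rr > 0,
            cfg$n_confounders >= 0L,
            cfg$codes_per_dimension >= 1L,
            cfg$split_n_children >= 1L,
            cfg$occurrence_geom_prob > 0, cfg$occurrence_geom_prob <= 1,
            cfg$noise_code_rate >= 0,
            cfg$ccs_missing_fraction >= 0, cfg$ccs_missing_fraction < 1)
  props <- c(cfg$p_exposed_target, cfg$baseline_risk, cfg$confounder_prevalences)
  if (any(props <= 0 | props >= 1))
    stop("all proportions must lie strictly in (0, 1)")
  if (length(cfg$confounder_prevalences) != cfg$n_confounders ||
      length(cfg$confounder_exposure_log_ors) != cfg$n_confounders ||
      length(cfg$confounder_outcome_log_rrs) != cfg$n_confounders)
    stop("confounder parameter vectors must all have length n_confounders")
  br <- cfg$hierarchy_branching
  if (!is.list(br) || !all(c("atc", "dx") %in% names(br)))
    stop("hierarchy_branching must be a list with elements 'atc' and 'dx'")
  if (length(br$atc) != 5L || any(br$atc < 1L))
    stop("hierarchy_branching$atc must give 5 per-level branching counts >= 1")
  if (length(br$dx) != 3L || any(br$dx < 1L))
    stop("hierarchy_branching$dx must give 3 per-level branching counts >= 1")
  invisible(cfg)
}
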