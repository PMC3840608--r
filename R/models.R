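#' Crude risk ratio with Katz 95% confidence interval
#'
#' \code{RR = (a/N1)/(c/N0)} with the log-scale interval
#' \code{exp(ln RR +/- 1.96 sqrt(1/a - 1/N1 + 1/c - 1/N0))}. With zero cases
#' in either arm the interval is undefined and flagged.
#'
#' @param exposed_cases,exposed_n cases and total in the exposed arm.
#' @param unexposed_cases,unexposed_n cases and total in the unexposed arm.
#' @return A list with \code{rr, ci_lower, ci_upper, log_rr, se, undefined}.
#' @examples
#' crude_risk_ratio(46, 7197, 71, 11632)  # RR 1.05, CI 0.72-1.52
#' @export
crude_risk_ratio <- function(exposed_cases, exposed_n,
                             unexposed_cases, unexposed_n) {
  stopifnot(exposed_cases >= 0, unexposed_cases >= 0,
            exposed_n > 0, unexposed_n > 0)
  rr <- (exposed_cases / exposed_n) / (unexposed_cases / unexposed_n)
  if (exposed_cases == 0 || unexposed_cases == 0)
    return(list(rr = rr, ci_lower = NA_real_, ci_upper = NA_real_,
                log_rr = log(rr), se = NA_real_, undefined = TRUE))
  se <- sqrt(1 / exposed_cases - 1 / exposed_n +
             1 / unexposed_cases - 1 / unexposed_n)
  list(rr = rr, ci_lower = exp(log(rr) - 1.96 * se),
       ci_upper = exp(log(rr) + 1.96 * se),
       log_rr = log(rr), se = se, undefined = FALSE)
}

# drop constant and duplicated columns of a design matrix, returning the
# reduced matrix with the dropped names recorded as attributes
prune_design <- function(X) {
  if (is.null(X) || ncol(X) == 0L)
    return(structure(X, dropped_constant = character(),
                     dropped_duplicate = character()))
  keep_const <- apply(X, 2L, function(v) length(unique(v)) > 1L)
  dropped_constant <- colnames(X)[!keep_const]
  X <- X[, keep_const, drop = FALSE]
  dup <- duplicated(lapply(seq_len(ncol(X)), function(j) X[, j]))
  dropped_duplicate <- colnames(X)[dup]
  X <- X[, !dup, drop = FALSE]
  structure(X, dropped_constant = dropped_constant,
            dropped_duplicate = dropped_duplicate)
}

#' Fit a propensity score by maximum-likelihood logistic regression
#'
#' Exposure is regressed on the supplied covariate matrix. Constant and
#' duplicated columns are dropped up front; covariates implicated in (quasi-)
#' separation (absolute coefficient above 15 with a non-converged or
#' boundary fit) are dropped with a second fit attempt, and their names
#' recorded. Deterministic given the data.
#'
#' @param exposed 0/1 exposure vector.
#' @param covariates numeric matrix (patients x covariates) combining basic,
#'   optional extended, and selected empirical covariates.
#' @return An object of class \code{propensity_fit}: \code{scores} (fitted
#'   probabilities in (0,1)), \code{coefficients}, \code{converged},
#'   \code{dropped} (named list of pruned/separation-dropped columns).
#' @export
fit_propensity_score <- function(exposed, covariates) {
  X <- prune_design(as.matrix(covariates))
  dropped <- list(constant = attr(X, "dropped_constant"),
                  duplicate = attr(X, "dropped_duplicate"),
                  separation = character())
  fit_once <- function(M) {
    suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, M), exposed,
                             family = binomial(),
                             control = list(maxit = 50L)))
  }
  fit <- fit_once(X)
  co <- fit$coefficients[-1L]
  suspect <- names(co)[!is.na(co) & abs(co) > 15]
  if ((!fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
       any(fit$fitted.values < 1e-10)) && length(suspect)) {
    dropped$separation <- suspect
    X <- X[, setdiff(colnames(X), suspect), drop = FALSE]
    fit <- fit_once(X)
  }
  if (!fit$converged)
    stop("propensity model did not converge; suspect covariates: ",
         paste(if (length(suspect)) suspect else "none identified",
               collapse = ", "))
  structure(list(scores = pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12),
                 coefficients = fit$coefficients,
                 converged = fit$converged, dropped = dropped),
            class = "propensity_fit")
}

#' Assign propensity-score deciles
#'
#' Cut points are the 10%, 20%, ..., 90% empirical quantiles of the pooled
#' score distribution (both treatment groups together); scores tied exactly at
#' a boundary all fall in the lower stratum; cut points made identical by mass
#' ties are merged (reported via the \code{"n_merged"} attribute).
#'
#' @param scores propensity scores from [fit_propensity_score()].
#' @param n_strata number of strata (default 10).
#' @return Integer stratum assignment (1 = lowest), with attributes
#'   \code{"breaks"} and \code{"n_merged"}.
#' @export
assign_ps_deciles <- function(scores, n_strata = 10L) {
  br <- quantile(scores, probs = seq_len(n_strata - 1L) / n_strata,
                 type = 7, names = FALSE)
  ubr <- unique(br)
  n_merged <- length(br) - length(ubr)
  if (length(unique(scores)) < n_strata)
    warning("fewer than ", n_strata, " distinct scores; degenerate strata")
  stratum <- as.integer(cut(scores, breaks = c(-Inf, ubr, Inf), right = TRUE,
                            labels = FALSE))
  attr(stratum, "breaks") <- ubr
  attr(stratum, "n_merged") <- n_merged
  stratum
}

# 0/1 dummy columns for a stratum vector, reference = first stratum
stratum_indicators <- function(stratum) {
  lev <- sort(unique(stratum))
  if (length(lev) <= 1L) return(NULL)
  X <- vapply(lev[-1L], function(l) as.numeric(stratum == l),
              numeric(length(stratum)))
  colnames(X) <- paste0("ps_decile_", lev[-1L])
  X
}

#' Estimate an adjusted risk ratio by log-binomial regression
#'
#' Fits a log-link binomial model of the outcome on exposure plus adjusters;
#' the exponentiated exposure coefficient is the risk ratio, with a Wald
#' interval on the log scale. When the log-binomial fit fails or does not
#' converge (common with rare outcomes), falls back to a modified-Poisson
#' model with robust (sandwich, HC0) variance and flags it.
#'
#' @param outcome,exposure 0/1 vectors.
#' @param adjusters optional numeric matrix of adjustment covariates.
#' @return A list with \code{rr, ci_lower, ci_upper, log_rr, se, converged,
#'   fallback_used, model} (\code{"log-binomial"} or
#'   \code{"poisson-robust"}).
#' @export
estimate_adjusted_rr <- function(outcome, exposure, adjusters = NULL) {
  if (sum(outcome) == 0L) stop("no outcome events; risk ratio undefined")
  X <- cbind(exposure = exposure,
             if (!is.null(adjusters)) prune_design(as.matrix(adjusters)))
  dat <- data.frame(y = outcome)
  dat$X <- X
  start <- c(log(max(mean(outcome), 1e-10)), rep(0, ncol(X)))

  fit <- tryCatch(
    suppressWarnings(glm(y ~ X, data = dat, family = binomial(link = "log"),
                         start = start, control = list(maxit = 100L))),
    error = function(e) NULL)
  # a one-column matrix term is named plain "X" by model.matrix
  exposure_coef <- if (ncol(X) == 1L) "X" else "Xexposure"
  ok <- !is.null(fit) && fit$converged &&
    !is.na(coef(fit)[exposure_coef]) &&
    all(fit$fitted.values < 1 - 1e-10)
  if (ok) {
    b <- unname(coef(fit)[exposure_coef])
    se <- sqrt(vcov(fit)[exposure_coef, exposure_coef])
    return(list(rr = exp(b), ci_lower = exp(b - 1.96 * se),
                ci_upper = exp(b + 1.96 * se), log_rr = b,
                se = unname(se), converged = TRUE, fallback_used = FALSE,
                model = "log-binomial"))
  }

  pfit <- tryCatch(
    suppressWarnings(glm(y ~ X, data = dat, family = poisson(),
                         control = list(maxit = 100L))),
    error = function(e) NULL)
  if (is.null(pfit) || !pfit$converged || is.na(coef(pfit)[exposure_coef]))
    stop("both the log-binomial and the modified-Poisson fallback failed",
         if (!is.null(pfit) && is.na(coef(pfit)[exposure_coef]))
           " (exposure collinear with adjusters)" else "")
  vc <- sandwich::vcovHC(pfit, type = "HC0")
  b <- unname(coef(pfit)[exposure_coef])
  se <- sqrt(vc[exposure_coef, exposure_coef])
  list(rr = exp(b), ci_lower = exp(b - 1.96 * se),
       ci_upper = exp(b + 1.96 * se), log_rr = b,
       se = unname(se), converged = TRUE, fallback_used = TRUE,
       model = "poisson-robust")
}

# design matrix of the basic covariates: age (continuous), sex, index-year
# indicator(s); a single-year cohort contributes no year column
basic_covariate_matrix <- function(cohort) {
  X <- cbind(age = cohort$age, sex = cohort$sex)
  yrs <- sort(unique(cohort$index_year))
  if (length(yrs) > 1L)
    for (y in yrs[-1L])
      X <- cbind(X, as.numeric(cohort$index_year == y))
  if (length(yrs) > 1L)
    colnames(X) <- c("age", "sex", paste0("year_", yrs[-1L]))
  X
}

MODEL_NAMES <- c("crude", "basic", "basic_extended", "basic_hdps",
                 "basic_extended_hdps")

#' Fit the nested suite of crude and adjusted risk-ratio models
#'
#' The five specifications: (1) unadjusted crude (closed form); (2) basic
#' covariates (age, sex, index year); (3) basic plus pre-selected extended
#' covariates; (4) basic plus empirical covariates, adjusted through deciles
#' of a propensity score fitted on basic + selected covariates; (5) as (4)
#' with the extended covariates also in the propensity model. Covariate
#' selection runs once per (cohort, scenario) and is shared by models 4 and 5.
#'
#' @param cohort cohort data.frame.
#' @param events event table (pre-aggregation).
#' @param scenario an [aggregation_scenario()]; applied to \code{events}
#'   before selection.
#' @param maps hierarchy maps for the scenario (see
#'   [apply_aggregation_scenario()]).
#' @param hdps hdps_config for the covariate engine.
#' @param models subset of \code{c("crude","basic","basic_extended",
#'   "basic_hdps","basic_extended_hdps")} to fit.
#' @return A list of class \code{model_suite}: \code{estimates} (one row per
#'   model: rr, ci bounds, converged, fallback_used, model), \code{selected}
#'   (the selected-covariate table), \code{scenario_label},
#'   \code{aggregation_report}.
#' @export
run_model_suite <- function(cohort, events, scenario = aggregation_scenario(),
                            maps = NULL, hdps = hdps_config(),
                            models = MODEL_NAMES) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  ev <- apply_aggregation_scenario(events, scenario, maps)

  need_hdps <- any(c("basic_hdps", "basic_extended_hdps") %in% models)
  sel <- NULL; Xh <- NULL
  if (need_hdps) {
    hres <- hdps_covariates(ev, cohort, hdps)
    sel <- hres$selected
    Xh <- build_indicator_matrix(ev, sel, cohort$patient_id)
  }
  Xb <- basic_covariate_matrix(cohort)
  ext_cols <- extended_flag_columns(cohort)
  Xe <- if (length(ext_cols)) as.matrix(cohort[ext_cols]) else NULL

  est <- list()
  add <- function(name, e) {
    est[[name]] <<- data.frame(model = name, rr = e$rr, ci_lower = e$ci_lower,
                               ci_upper = e$ci_upper,
                               converged = e$converged %||% TRUE,
                               fallback_used = e$fallback_used %||% FALSE,
                               fit = e$model %||% "closed-form",
                               stringsAsFactors = FALSE)
  }
  y <- cohort$outcome; tr <- cohort$exposed

  if ("crude" %in% models) {
    cr <- crude_risk_ratio(sum(y[tr == 1L]), sum(tr == 1L),
                           sum(y[tr == 0L]), sum(tr == 0L))
    add("crude", list(rr = cr$rr, ci_lower = cr$ci_lower,
                      ci_upper = cr$ci_upper, converged = !cr$undefined))
  }
  if ("basic" %in% models)
    add("basic", estimate_adjusted_rr(y, tr, Xb))
  if ("basic_extended" %in% models)
    add("basic_extended", estimate_adjusted_rr(y, tr, cbind(Xb, Xe)))
  if ("basic_hdps" %in% models) {
    ps <- fit_propensity_score(tr, cbind(Xb, Xh))
    dec <- assign_ps_deciles(ps$scores)
    add("basic_hdps", estimate_adjusted_rr(y, tr, stratum_indicators(dec)))
  }
  if ("basic_extended_hdps" %in% models) {
    ps <- fit_propensity_score(tr, cbind(Xb, Xe, Xh))
    dec <- assign_ps_deciles(ps$scores)
    add("basic_extended_hdps",
        estimate_adjusted_rr(y, tr, stratum_indicators(dec)))
  }

  structure(list(estimates = do.call(rbind, est[models[models %in% names(est)]]),
                 selected = sel, scenario_label = scenario$label,
                 aggregation_report = attr(ev, "aggregation_report")),
            class = "model_suite")
}
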