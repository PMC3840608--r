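CONDITION_TABLE <- data.frame(
  condition_id = 1:6,
  axis = rep(c("size", "outcome", "exposure"), each = 2L),
  fraction = rep(c(0.5, 0.2), 3L),
  stringsAsFactors = FALSE
)

#' Specify one resampling condition
#'
#' The six canonical conditions thin the full cohort along one axis:
#' 1/2 = 50%/20% simple random samples of the whole cohort (size);
#' 3/4 = 50%/20% of the cases kept as cases, the rest re-coded to non-cases
#' (outcome incidence); 5/6 = 50%/20% of the exposed kept, removed exposed
#' replaced by randomly drawn unexposed patients (exposure prevalence).
#'
#' @param condition_id 1..6; axis and fraction are filled in from the
#'   canonical table when omitted.
#' @param axis one of \code{"size", "outcome", "exposure"}.
#' @param fraction thinning fraction in (0, 1].
#' @param n_replicates number of replicate samples (default 100).
#' @param seed root seed for the condition's substreams.
#' @return An object of class \code{condition_spec}.
#' @export
condition_spec <- function(condition_id = NULL, axis = NULL, fraction = NULL,
                           n_replicates = 100L, seed = 1L) {
  if (!is.null(condition_id)) {
    condition_id <- as.integer(condition_id)
    stopifnot(condition_id %in% 1:6)
    row <- CONDITION_TABLE[condition_id, ]
    if (!is.null(axis) && !identical(axis, row$axis))
      stop("condition ", condition_id, " is the ", row$axis, " axis")
    if (!is.null(fraction) && fraction != row$fraction)
      stop("condition ", condition_id, " uses fraction ", row$fraction)
    axis <- row$axis; fraction <- row$fraction
  } else {
    axis <- match.arg(axis, c("size", "outcome", "exposure"))
    stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
    hit <- which(CONDITION_TABLE$axis == axis &
                 CONDITION_TABLE$fraction == fraction)
    condition_id <- if (length(hit)) CONDITION_TABLE$condition_id[hit] else NA_integer_
  }
  structure(list(condition_id = condition_id, axis = axis, fraction = fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "condition_spec")
}

restrict_events <- function(events, patient_ids) {
  events[events$patient_id %in% patient_ids, , drop = FALSE]
}

#' Simple random subsample of the cohort
#'
#' Draws \code{ceiling(fraction * N)} patients without replacement and
#' restricts the event table to them. Uses the current RNG stream.
#'
#' @param cohort,events the parent cohort and events.
#' @param fraction sampling fraction in (0, 1].
#' @return A list with elements \code{cohort} and \code{events}.
#' @export
draw_size_sample <- function(cohort, events, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- ceiling(fraction * nrow(cohort))
  keep <- sort(sample(nrow(cohort), m))
  sub <- cohort[keep, , drop = FALSE]
  Z <- attr(cohort, "confounders")
  if (!is.null(Z)) attr(sub, "confounders") <- Z[keep, , drop = FALSE]
  rownames(sub) <- NULL
  list(cohort = sub, events = restrict_events(events, sub$patient_id))
}

#' Thin the outcome incidence
#'
#' Retains every patient; \code{ceiling(fraction * n_cases)} randomly chosen
#' cases keep their outcome, the remaining cases are re-coded to non-cases
#' (records kept, not dropped), so only the outcome vector changes.
#'
#' @inheritParams draw_size_sample
#' @return A list with elements \code{cohort} and \code{events}.
#' @export
draw_outcome_thinned_sample <- function(cohort, events, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  cases <- which(cohort$outcome == 1L)
  if (length(cases) == 0L) stop("cohort has no cases to thin")
  keep_n <- ceiling(fraction * length(cases))
  keep <- sample(cases, keep_n)
  out <- cohort
  out$outcome[setdiff(cases, keep)] <- 0L
  list(cohort = out, events = events)
}

#' Thin the exposure prevalence
#'
#' Retains all unexposed patients; keeps \code{ceiling(fraction * n_exposed)}
#' randomly chosen exposed patients; the removed exposed are replaced by an
#' equal number of patients drawn uniformly with replacement from the
#' unexposed pool, appended as duplicate records under fresh patient
#' identifiers with their events copied. The record count equals the original
#' cohort size.
#'
#' @inheritParams draw_size_sample
#' @return A list with elements \code{cohort} and \code{events}.
#' @export
draw_exposure_thinned_sample <- function(cohort, events, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  expo <- which(cohort$exposed == 1L)
  unex <- which(cohort$exposed == 0L)
  if (length(expo) == 0L || length(unex) == 0L)
    stop("need at least one exposed and one unexposed patient")
  keep_n <- ceiling(fraction * length(expo))
  keep_expo <- sort(sample(expo, keep_n))
  n_replace <- length(expo) - keep_n
  rows <- sort(c(keep_expo, unex))
  sub <- cohort[rows, , drop = FALSE]
  ev <- restrict_events(events, sub$patient_id)
  if (n_replace > 0L) {
    src_rows <- sample(unex, n_replace, replace = TRUE)
    dup <- cohort[src_rows, , drop = FALSE]
    new_ids <- max(cohort$patient_id) + seq_len(n_replace)
    old_ids <- dup$patient_id
    dup$patient_id <- new_ids
    sub <- rbind(sub, dup)
    dup_ev <- data.table::as.data.table(events)[
      data.table::data.table(patient_id = old_ids, .new = new_ids),
      on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(dup_ev)) {
      dup_ev[, patient_id := .new]
      dup_ev[, .new := NULL]
      data.table::setDF(dup_ev)
      ev <- rbind(ev, dup_ev)
    }
  }
  rownames(sub) <- NULL
  attr(sub, "confounders") <- NULL
  list(cohort = sub, events = ev)
}

#' Draw one replicate sample of a condition
#'
#' Deterministic given \code{(spec$seed, spec$condition_id, replicate)}: each
#' replicate runs on its own child seed, so any sample can be regenerated in
#' isolation and the sequence never shifts when other replicates are added.
#'
#' @param cohort,events the parent cohort and events.
#' @param spec a [condition_spec()].
#' @param replicate replicate index (1-based).
#' @return A list with elements \code{cohort}, \code{events},
#'   \code{replicate}, \code{seed}.
#' @export
draw_condition_sample <- function(cohort, events, spec, replicate) {
  stopifnot(inherits(spec, "condition_spec"))
  cs <- child_seed(spec$seed, spec$condition_id %||% 0L, replicate)
  smp <- with_local_seed(cs, switch(
    spec$axis,
    size = draw_size_sample(cohort, events, spec$fraction),
    outcome = draw_outcome_thinned_sample(cohort, events, spec$fraction),
    exposure = draw_exposure_thinned_sample(cohort, events, spec$fraction)))
  smp$replicate <- replicate
  smp$seed <- cs
  smp
}

#' Generate (or map over) all replicate samples of a condition
#'
#' @param cohort,events the parent cohort and events.
#' @param spec a [condition_spec()].
#' @param FUN function applied to each sample (default \code{identity});
#'   supplying a summarising function avoids holding all samples in memory.
#' @return A list of length \code{spec$n_replicates} with the \code{FUN}
#'   results.
#' @export
generate_condition_samples <- function(cohort, events, spec, FUN = identity) {
  lapply(seq_len(spec$n_replicates), function(r)
    FUN(draw_condition_sample(cohort, events, spec, r)))
}

#' Manifest of the samples a condition spec generates
#'
#' One row per replicate: sizes, exposed and case counts, and the child seed
#' sufficient to regenerate the sample exactly.
#'
#' @inheritParams generate_condition_samples
#' @param file optional CSV path.
#' @return data.frame with columns \code{condition_id, replicate, n,
#'   n_exposed, n_cases, seed}.
#' @export
sample_manifest <- function(cohort, events, spec, file = NULL) {
  rows <- generate_condition_samples(cohort, events, spec, function(s) {
    data.frame(condition_id = spec$condition_id, replicate = s$replicate,
               n = nrow(s$cohort), n_exposed = sum(s$cohort$exposed),
               n_cases = sum(s$cohort$outcome), seed = s$seed)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
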