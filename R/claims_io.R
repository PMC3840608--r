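#' Write a cohort and its code events to CSV claims tables
#'
#' Writes \code{patients.csv} (patient_id, age, sex, index_year, exposed,
#' outcome, one column per extended flag) and \code{events.csv} (patient_id,
#' dimension, code, n_occurrences) under \code{path}.
#'
#' @param cohort a cohort data.frame.
#' @param events an event data.frame.
#' @param path directory to write into (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_claims_tables <- function(cohort, events, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(path, "patients.csv")
  ef <- file.path(path, "events.csv")
  write.csv(as.data.frame(cohort), pf, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(events), ef, row.names = FALSE, quote = FALSE)
  invisible(c(patients = pf, events = ef))
}

#' Read claims tables written by [write_claims_tables()]
#'
#' Validates the documented layout: unique patient identifiers, binary
#' exposure/outcome, recognised dimensions and occurrence counts of at least
#' one. Malformed rows produce an error naming the offending row and column.
#'
#' @param path directory containing \code{patients.csv} and \code{events.csv}.
#' @return A list with elements \code{cohort} and \code{events}. The cohort
#'   carries no latent confounder matrix (user-supplied data never does).
#' @export
read_claims_tables <- function(path) {
  pf <- file.path(path, "patients.csv")
  ef <- file.path(path, "events.csv")
  if (!file.exists(pf) || !file.exists(ef))
    stop("expected patients.csv and events.csv under ", path)
  cohort <- read.csv(pf, stringsAsFactors = FALSE)
  events <- read.csv(ef, stringsAsFactors = FALSE,
                     colClasses = c(code = "character"))

  need <- c("patient_id", "age", "sex", "index_year", "exposed", "outcome")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("patients.csv: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id)) {
    r <- which(duplicated(cohort$patient_id))[1L]
    stop("patients.csv row ", r, ", column patient_id: duplicate identifier ",
         cohort$patient_id[r])
  }
  for (col in c("exposed", "outcome")) {
    bad <- which(!cohort[[col]] %in% c(0L, 1L))
    if (length(bad))
      stop("patients.csv row ", bad[1L], ", column ", col,
           ": value must be 0 or 1")
  }

  need_ev <- c("patient_id", "dimension", "code", "n_occurrences")
  miss <- setdiff(need_ev, names(events))
  if (length(miss))
    stop("events.csv: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!events$dimension %in% CLAIMS_DIMENSIONS)
  if (length(bad))
    stop("events.csv row ", bad[1L], ", column dimension: unknown dimension '",
         events$dimension[bad[1L]], "'")
  bad <- which(!is.finite(events$n_occurrences) | events$n_occurrences < 1)
  if (length(bad))
    stop("events.csv row ", bad[1L], ", column n_occurrences: ",
         "count must be >= 1")
  bad <- which(!events$patient_id %in% cohort$patient_id)
  if (length(bad))
    stop("events.csv row ", bad[1L], ", column patient_id: unknown patient ",
         events$patient_id[bad[1L]])

  class(cohort) <- c("claims_cohort", "data.frame")
  list(cohort = cohort, events = events)
}
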