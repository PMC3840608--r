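ATC_LEVEL_WIDTHS <- c(1L, 3L, 4L, 5L, 7L)

RX_SCHEMES <- c("generic", "atc1", "atc2", "atc3", "atc4", "atc5", "none")
DX_SCHEMES <- c("icd5", "icd4", "icd3", "ccs1", "ccs2", "ccs3", "ccs4",
                "ccs_universal", "none")

#' Define a code-aggregation scenario
#'
#' A scenario pairs one medication setting with one diagnosis setting. The
#' base scenario is \code{(generic, icd5)}: generic (substance-level) drug
#' codes and up-to-5-digit diagnosis granularity. \code{"none"} drops the
#' dimension's events entirely. Procedure codes are never aggregated.
#'
#' @param rx one of \code{generic, atc1..atc5, none}.
#' @param dx one of \code{icd5, icd4, icd3, ccs1..ccs4, ccs_universal, none}.
#' @param label optional display label; defaults to \code{"rx+dx"}.
#' @return An object of class \code{aggregation_scenario}.
#' @export
aggregation_scenario <- function(rx = "generic", dx = "icd5", label = NULL) {
  rx <- match.arg(rx, RX_SCHEMES)
  dx <- match.arg(dx, DX_SCHEMES)
  structure(list(rx = rx, dx = dx, label = label %||% paste(rx, dx, sep = "+")),
            class = "aggregation_scenario")
}

#' Is this the base (no aggregation) scenario?
#' @param scenario an [aggregation_scenario()].
#' @return \code{TRUE} for \code{(generic, icd5)}.
#' @export
is_base_scenario <- function(scenario) {
  scenario$rx == "generic" && scenario$dx == "icd5"
}

#' Truncate ATC codes to a hierarchy level
#'
#' ATC codes have widths 1/3/4/5/7 at levels 1-5, so aggregation to level
#' \code{k} is truncation to the level-\code{k} prefix width. Codes already
#' shorter than the requested width are returned unchanged; the number of such
#' codes is attached as attribute \code{"n_short"}.
#'
#' @param code character vector of ATC codes.
#' @param level integer 1..5.
#' @return Character vector of truncated codes.
#' @examples
#' truncate_atc("B01AC04", 4)  # "B01AC"
#' truncate_atc("B01AA03", 1)  # "B"
#' @export
truncate_atc <- function(code, level) {
  stopifnot(length(level) == 1L, level %in% 1:5)
  if (any(!nzchar(code)) || any(is.na(code))) stop("empty ATC code")
  w <- ATC_LEVEL_WIDTHS[level]
  short <- nchar(code) < w
  out <- ifelse(short, code, substr(code, 1L, w))
  attr(out, "n_short") <- sum(short)
  out
}

#' Truncate ICD-9 diagnosis codes to 3 or 4 significant digits
#'
#' The decimal point is optional in the input and does not count towards the
#' digits; V/E prefixes count as part of the stem. Codes shorter than the
#' target are returned unchanged. Output is rendered with the decimal point
#' ("530.1"); the aggregation pipeline stores codes without it.
#'
#' @param code character vector of ICD-9 codes.
#' @param digits 3 or 4.
#' @return Character vector of truncated codes (decimal rendering).
#' @examples
#' truncate_icd9("530.11", 4)  # "530.1"
#' truncate_icd9("530.11", 3)  # "530"
#' @export
truncate_icd9 <- function(code, digits) {
  stopifnot(length(digits) == 1L, digits %in% c(3L, 4L))
  format_icd9(substr(normalize_icd9(code), 1L, digits))
}

#' Read a multi-level diagnosis cross-map
#'
#' Expects columns \code{icd9_code, ccs_level1, ccs_level2, ccs_level3,
#' ccs_level4}; empty cells mean the code has no grouping at that level (the
#' layout of the AHRQ multi-level cross-map after trivial reformatting). Codes
#' are normalized (decimal points stripped) on load. Hierarchical consistency
#' is enforced: a level present while a shallower level is missing is an
#' error naming the offending codes.
#'
#' @param file path to the CSV, or a data.frame already in that layout.
#' @return A \code{ccs_map} data.frame keyed by normalized code.
#' @export
read_ccs_map <- function(file) {
  map <- if (is.data.frame(file)) file
         else read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("icd9_code", paste0("ccs_level", 1:4))
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("diagnosis cross-map: missing column(s) ", paste(miss, collapse = ", "))
  map <- map[need]
  map$icd9_code <- normalize_icd9(map$icd9_code)
  for (j in 2:5) {
    empty <- is.na(map[[j]]) | !nzchar(trimws(map[[j]]))
    map[[j]][empty] <- NA_character_
  }
  for (j in 3:5) {
    bad <- !is.na(map[[j]]) & is.na(map[[j - 1L]])
    if (any(bad))
      stop("diagnosis cross-map: level ", j - 1L, " present while level ",
           j - 2L, " missing for code(s) ",
           paste(head(map$icd9_code[bad], 5L), collapse = ", "))
  }
  if (anyDuplicated(map$icd9_code))
    stop("diagnosis cross-map: duplicated code(s)")
  class(map) <- c("ccs_map", "data.frame")
  map
}

#' Read a flat ATC code list
#'
#' Expects columns \code{code, name}; the level of each row is inferred from
#' the code width. Used only for reporting/labels - truncation itself needs no
#' dictionary.
#'
#' @param file path to the CSV, or a data.frame.
#' @return A data.frame with columns \code{code, name, level}.
#' @export
read_atc_map <- function(file) {
  map <- if (is.data.frame(file)) file else read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(map)))
    stop("ATC map: expected columns code, name")
  lv <- match(nchar(map$code), ATC_LEVEL_WIDTHS)
  if (anyNA(lv))
    stop("ATC map: code width must be one of 1, 3, 4, 5, 7 characters")
  map$level <- lv
  map
}

#' Map ICD-9 codes to multi-level diagnosis groups
#'
#' At a fixed level, returns that level's label; at \code{"universal"}, the
#' deepest available label per code. Codes absent from the map (or lacking the
#' requested level) pass through unchanged and are counted in the
#' \code{"n_unmapped"} attribute - dropping them would silently delete
#' confounder signal.
#'
#' @param code character vector of ICD-9 codes (either decimal dialect).
#' @param level 1..4 or \code{"universal"}.
#' @param map a [read_ccs_map()] result.
#' @return Character vector of group labels (or pass-through codes), with
#'   attribute \code{"n_unmapped"}.
#' @export
map_to_ccs <- function(code, level, map) {
  stopifnot(inherits(map, "ccs_map"))
  norm <- normalize_icd9(code)
  i <- match(norm, map$icd9_code)
  if (identical(level, "universal")) {
    lab <- rep(NA_character_, length(code))
    for (j in 5:2) {                       # deepest available level wins
      cand <- map[[j]][i]
      lab[is.na(lab) & !is.na(cand)] <- cand[is.na(lab) & !is.na(cand)]
    }
  } else {
    stopifnot(level %in% 1:4)
    lab <- map[[paste0("ccs_level", level)]][i]
  }
  unmapped <- is.na(lab)
  lab[unmapped] <- code[unmapped]        # pass through unchanged (idempotent)
  attr(lab, "n_unmapped") <- sum(unmapped)
  lab
}

#' Apply an aggregation scenario to an event table
#'
#' Transforms pharmacy codes per the scenario's medication setting and both
#' diagnosis dimensions per its diagnosis setting; \code{"none"} settings drop
#' the dimension's events entirely; procedure dimensions always pass through
#' unchanged. Events that collapse onto the same (patient, dimension, code)
#' are merged by summing occurrence counts, so recurrence levels remain
#' meaningful after aggregation.
#'
#' @param events event data.frame.
#' @param scenario an [aggregation_scenario()].
#' @param maps list with element \code{ccs} (a [read_ccs_map()] result),
#'   required for CCS settings; a [generate_toy_hierarchies()] object works.
#' @return The aggregated event table, with attribute \code{"aggregation_report"}
#'   (counts of unmapped and short codes).
#' @export
apply_aggregation_scenario <- function(events, scenario, maps = NULL) {
  stopifnot(inherits(scenario, "aggregation_scenario"))
  report <- list(n_unmapped = 0L, n_short = 0L)
  ev <- as.data.frame(events)

  if (scenario$rx == "none") {
    ev <- ev[ev$dimension != "pharmacy", , drop = FALSE]
  } else if (!scenario$rx %in% c("generic", "atc5")) {
    lvl <- as.integer(substr(scenario$rx, 4L, 4L))
    i <- ev$dimension == "pharmacy"
    newc <- truncate_atc(ev$code[i], lvl)
    report$n_short <- attr(newc, "n_short")
    ev$code[i] <- as.character(newc)
  }

  dxi <- ev$dimension %in% c("dx_inpatient", "dx_outpatient")
  if (scenario$dx == "none") {
    ev <- ev[!dxi, , drop = FALSE]
  } else if (scenario$dx %in% c("icd3", "icd4")) {
    d <- if (scenario$dx == "icd3") 3L else 4L
    ev$code[dxi] <- normalize_icd9(truncate_icd9(ev$code[dxi], d))
  } else if (scenario$dx != "icd5") {
    ccs <- if (inherits(maps, "ccs_map")) maps else maps$ccs
    if (is.null(ccs))
      stop("scenario '", scenario$label, "' needs a diagnosis cross-map")
    if (!inherits(ccs, "ccs_map")) ccs <- read_ccs_map(ccs)
    lvl <- if (scenario$dx == "ccs_universal") "universal"
           else as.integer(substr(scenario$dx, 4L, 4L))
    lab <- map_to_ccs(ev$code[dxi], lvl, ccs)
    report$n_unmapped <- attr(lab, "n_unmapped")
    ev$code[dxi] <- as.character(lab)
  }

  dt <- data.table::as.data.table(ev)
  dt <- dt[, list(n_occurrences = sum(n_occurrences)),
           by = c("patient_id", "dimension", "code")]
  data.table::setorder(dt, patient_id, dimension, code)
  data.table::setDF(dt)
  attr(dt, "aggregation_report") <- report
  dt
}
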