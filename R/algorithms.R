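#' Define one case-finding algorithm
#'
#' An algorithm is a triple of code-list tier, record-source rule and
#' peri-diagnosis time window, plus two policy switches:
#'
#' * `source_rule`: `H1` (1+ qualifying hospitalization), `H1_OR_O2`
#'   (1+ hospitalization or 2+ outpatient), `H1_OR_O1` (1+ hospitalization
#'   or 1+ outpatient).
#' * `window`: `PRE90_POST90` (+/- 3 months around diagnosis),
#'   `PRE180_POST180` (+/- 6 months), `PRE90_NOLIMIT` (3 months before
#'   diagnosis, no end to follow-up).
#' * `ed_policy`: emergency-department claims counted with the outpatient
#'   arm (`ED_AS_OUTPATIENT`, default — ED records are ambulatory) or
#'   ignored (`ED_IGNORED`).
#' * `outpatient_units`: `"distinct_dates"` (default) counts distinct
#'   service dates among qualifying outpatient claims, so same-day duplicate
#'   billing rows cannot satisfy the 2+ threshold; `"rows"` counts raw rows.
#'
#' When `algorithm_number` (1-27) is given it must agree with the canonical
#' ordering used by [enumerate_algorithms()].
#'
#' @param tier One of `CONSERVATIVE`, `LESS_CONSERVATIVE`, `INCLUSIVE`.
#' @param source_rule One of `H1`, `H1_OR_O2`, `H1_OR_O1`.
#' @param window One of `PRE90_POST90`, `PRE180_POST180`, `PRE90_NOLIMIT`.
#' @param ed_policy `ED_AS_OUTPATIENT` or `ED_IGNORED`.
#' @param algorithm_number Optional integer 1-27.
#' @param outpatient_units `"distinct_dates"` or `"rows"`.
#' @return An object of class `algorithm_config`.
#' @export
#' @examples
#' algorithm_config("CONSERVATIVE", "H1_OR_O1", "PRE180_POST180",
#'                  algorithm_number = 12)
algorithm_config <- function(tier, source_rule, window,
                             ed_policy = "ED_AS_OUTPATIENT",
                             algorithm_number = NULL,
                             outpatient_units = c("distinct_dates", "rows")) {
  tier <- match.arg(tier, TIER_LEVELS)
  source_rule <- match.arg(source_rule, RULE_LEVELS)
  window <- match.arg(window, WINDOW_LEVELS)
  ed_policy <- match.arg(ed_policy, ED_LEVELS)
  outpatient_units <- match.arg(outpatient_units)
  if (!is.null(algorithm_number)) {
    algorithm_number <- as.integer(algorithm_number)
    if (is.na(algorithm_number) || algorithm_number < 1 ||
        algorithm_number > 27) {
      stop("algorithm_number must be an integer between 1 and 27",
           call. = FALSE)
    }
    expct <- algorithm_fields(algorithm_number)
    if (expct$tier != tier || expct$source_rule != source_rule ||
        expct$window != window) {
      stop(sprintf(
        "algorithm_number %d corresponds to (%s, %s, %s), not (%s, %s, %s)",
        algorithm_number, expct$window, expct$tier, expct$source_rule,
        window, tier, source_rule), call. = FALSE)
    }
  }
  structure(list(tier = tier, source_rule = source_rule, window = window,
                 ed_policy = ed_policy, algorithm_number = algorithm_number,
                 outpatient_units = outpatient_units),
            class = "algorithm_config")
}

#' @export
print.algorithm_config <- function(x, ...) {
  cat(sprintf("<algorithm_config>%s tier=%s rule=%s window=%s ed=%s\n",
              if (is.null(x$algorithm_number)) "" else
                sprintf(" #%d", x$algorithm_number),
              x$tier, x$source_rule, x$window, x$ed_policy))
  invisible(x)
}

# canonical numbering: window-major, then tier, then source rule
algorithm_fields <- function(n) {
  n <- as.integer(n)
  list(window = WINDOW_LEVELS[((n - 1L) %/% 9L) + 1L],
       tier = TIER_LEVELS[(((n - 1L) %/% 3L) %% 3L) + 1L],
       source_rule = RULE_LEVELS[((n - 1L) %% 3L) + 1L])
}

#' Build one of the 27 numbered algorithms
#'
#' @param n Algorithm number, 1-27.
#' @param ... Passed to [algorithm_config()] (`ed_policy`,
#'   `outpatient_units`).
#' @return An [algorithm_config()].
#' @export
algorithm_from_number <- function(n, ...) {
  n <- suppressWarnings(as.integer(n))
  if (length(n) != 1 || is.na(n) || n < 1 || n > 27) {
    stop("algorithm number must be an integer between 1 and 27",
         call. = FALSE)
  }
  f <- algorithm_fields(n)
  algorithm_config(tier = f$tier, source_rule = f$source_rule,
                   window = f$window, algorithm_number = n, ...)
}

#' Enumerate the 27 case-finding algorithms in canonical order
#'
#' Windows in the order +/- 3 months, +/- 6 months, -3 months/no limit;
#' within each window the tiers conservative, less conservative, inclusive;
#' within each tier the source rules `H1`, `H1_OR_O2`, `H1_OR_O1`.
#' Algorithm 1 is (`PRE90_POST90`, `CONSERVATIVE`, `H1`); algorithm 12 is
#' (`PRE180_POST180`, `CONSERVATIVE`, `H1_OR_O1`).
#'
#' @param ... Passed to [algorithm_config()].
#' @return List of 27 [algorithm_config()] objects.
#' @export
enumerate_algorithms <- function(...) {
  lapply(1:27, algorithm_from_number, ...)
}

#' Peri-diagnosis window bounds
#'
#' Closed date interval around the diagnosis date: `PRE90_POST90` is
#' `[d - 90, d + 90]`, `PRE180_POST180` is `[d - 180, d + 180]` and
#' `PRE90_NOLIMIT` is `[d - 90, +Inf)` (`end` is `NA`, meaning unbounded;
#' in practice the effective upper bound is the claims extract's horizon).
#' The diagnosis date itself is always inside.
#'
#' @param diagnosis_date A `Date`.
#' @param window One of the window tokens.
#' @return List with `Date` elements `start` and `end` (`end = NA` when
#'   unbounded).
#' @export
#' @examples
#' window_bounds(as.Date("2006-06-01"), "PRE180_POST180")
window_bounds <- function(diagnosis_date, window) {
  window <- match.arg(window, WINDOW_LEVELS)
  d <- as_date_strict(diagnosis_date, "diagnosis_date")
  switch(window,
         PRE90_POST90 = list(start = d - 90, end = d + 90),
         PRE180_POST180 = list(start = d - 180, end = d + 180),
         PRE90_NOLIMIT = list(start = d - 90, end = as.Date(NA)))
}

in_window <- function(offset_days, window) {
  switch(window,
         PRE90_POST90 = offset_days >= -90 & offset_days <= 90,
         PRE180_POST180 = offset_days >= -180 & offset_days <= 180,
         PRE90_NOLIMIT = offset_days >= -90)
}

# one qualifying flag per claim row, cached over unique (version, codes)
claims_qualify <- function(claims, lst) {
  if (nrow(claims) == 0) return(logical(0))
  key <- paste(claims$icd_version, claims$codes, sep = "|")
  first <- !duplicated(key)
  uq <- vapply(which(first), function(i) {
    cs <- strsplit(claims$codes[i], ";", fixed = TRUE)[[1]]
    any(match_code(cs, claims$icd_version[i], lst))
  }, logical(1))
  uq[match(key, key[first])]
}

classify_core <- function(patients, claims, config, codelists) {
  lst <- if (inherits(codelists, "code_list")) codelists else
    codelists[[config$tier]]
  if (is.null(lst) || !inherits(lst, "code_list")) {
    stop("no code list available for tier ", config$tier, call. = FALSE)
  }
  out <- data.frame(patient_id = patients$patient_id,
                    predicted_m = rep("NEGATIVE", nrow(patients)),
                    n_hosp_qualifying = 0L,
                    n_outpatient_dates_qualifying = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(claims) > 0) {
    qual <- claims_qualify(claims, lst)
    dd <- patients$diagnosis_date[match(claims$patient_id,
                                        patients$patient_id)]
    off <- as.integer(claims$service_date - dd)
    sel <- qual & in_window(off, config$window)
    hosp_sel <- sel & claims$source == "HOSPITALIZATION"
    out_src <- if (config$ed_policy == "ED_AS_OUTPATIENT")
      c("OUTPATIENT", "ED") else "OUTPATIENT"
    outp_sel <- sel & claims$source %in% out_src
    if (any(hosp_sel)) {
      h <- data.table::data.table(pid = claims$patient_id[hosp_sel])
      h <- h[, list(N = .N), by = "pid"]
      out$n_hosp_qualifying[match(h$pid, out$patient_id)] <- h$N
    }
    if (any(outp_sel)) {
      o <- data.table::data.table(pid = claims$patient_id[outp_sel],
                                  date = claims$service_date[outp_sel])
      o <- if (config$outpatient_units == "distinct_dates") {
        o[, list(N = data.table::uniqueN(date)), by = "pid"]
      } else {
        o[, list(N = .N), by = "pid"]
      }
      out$n_outpatient_dates_qualifying[match(o$pid, out$patient_id)] <- o$N
    }
  }
  pos <- switch(config$source_rule,
                H1 = out$n_hosp_qualifying >= 1L,
                H1_OR_O2 = out$n_hosp_qualifying >= 1L |
                  out$n_outpatient_dates_qualifying >= 2L,
                H1_OR_O1 = out$n_hosp_qualifying >= 1L |
                  out$n_outpatient_dates_qualifying >= 1L)
  out$predicted_m <- ifelse(pos, "POSITIVE", "NEGATIVE")
  out
}

#' Classify one patient
#'
#' Counts the patient's qualifying claims inside the algorithm's window —
#' hospitalization claims, and distinct service dates among qualifying
#' outpatient (plus ED, per policy) claims — and applies the source rule.
#'
#' @param patient One-row data frame or list with at least `patient_id` and
#'   `diagnosis_date`.
#' @param claims Data frame of the patient's claims (may have zero rows).
#' @param config An [algorithm_config()].
#' @param codelists Named list of tier [code_list()]s (default
#'   [default_codelists()]) or a single `code_list`.
#' @return One-row data frame: `patient_id`, `predicted_m`
#'   (`POSITIVE`/`NEGATIVE`), `n_hosp_qualifying`,
#'   `n_outpatient_dates_qualifying`.
#' @export
classify_patient <- function(patient, claims, config,
                             codelists = default_codelists()) {
  stopifnot(inherits(config, "algorithm_config"))
  p <- data.frame(patient_id = as.character(patient$patient_id),
                  diagnosis_date = as_date_strict(patient$diagnosis_date,
                                                  "diagnosis_date"),
                  stringsAsFactors = FALSE)
  claims <- as.data.frame(claims, stringsAsFactors = FALSE)
  if (nrow(claims) && !all(claims$patient_id == p$patient_id)) {
    stop("claims belong to a different patient", call. = FALSE)
  }
  if (nrow(claims)) {
    claims$service_date <- as_date_strict(claims$service_date,
                                          "service_date")
    claims$codes <- normalize_codes_cell(claims$codes)
  }
  classify_core(p, claims, config, codelists)
}

#' Classify every patient in a cohort
#'
#' Applies one algorithm to the whole cohort.  Deterministic and independent
#' of claim ordering.
#'
#' @param x A [cohort()] object.
#' @inheritParams classify_patient
#' @return Data frame with one row per patient (in cohort order):
#'   `patient_id`, `predicted_m`, `n_hosp_qualifying`,
#'   `n_outpatient_dates_qualifying`.
#' @export
classify_cohort <- function(x, config, codelists = default_codelists()) {
  stopifnot(inherits(x, "claims_cohort"),
            inherits(config, "algorithm_config"))
  classify_core(x$patients, x$claims, config, codelists)
}
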