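#' Normalize a diagnosis code
#'
#' Canonical form used throughout the package: upper case, with dots and all
#' whitespace removed (`"C78.7"` becomes `"C787"`).  ICD-9 codes stay digit
#' strings (`"196.0"` becomes `"1960"`).  Source dialects differ in dot usage
#' (3-digit physician billing codes vs 4-5 character discharge abstract
#' codes), so prefix matching requires one canonical spelling.  The function
#' is idempotent.
#'
#' @param x Character vector of raw diagnosis codes.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("C78.7", " 196.0", "c79 5"))
normalize_code <- function(x) {
  gsub("[.[:space:]]+", "", toupper(as.character(x)))
}

as_date_strict <- function(x, what, allow_na = FALSE) {
  if (inherits(x, "Date")) {
    if (!allow_na && anyNA(x)) stop(sprintf("missing %s", what), call. = FALSE)
    return(x)
  }
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad)) {
    stop(sprintf("unparseable %s %s at row %s (expected YYYY-MM-DD)",
                 what, dQuote(x[bad[1]]), bad[1]), call. = FALSE)
  }
  if (!allow_na && anyNA(d)) {
    stop(sprintf("missing %s at row %d", what, which(is.na(d))[1]),
         call. = FALSE)
  }
  d
}

as_logical_strict <- function(x, what) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  out[lx == ""] <- NA
  bad <- which(!(lx %in% c("true", "t", "1", "false", "f", "0", "")))
  if (length(bad)) {
    stop(sprintf("invalid %s value %s at row %d (expected true/false)",
                 what, dQuote(lx[bad[1]]), bad[1]), call. = FALSE)
  }
  out
}

normalize_codes_cell <- function(codes) {
  vapply(strsplit(as.character(codes), ";", fixed = TRUE), function(cs) {
    cs <- normalize_code(cs)
    cs <- cs[nzchar(cs)]
    paste(cs, collapse = ";")
  }, character(1))
}

#' Construct a linked cohort + claims object
#'
#' The central container: one table of patients (the reference-standard side
#' of every 2x2) and one table of administrative claims (the evidence side),
#' pre-linked by `patient_id`.  The constructor coerces column types,
#' normalizes diagnosis codes and enforces the integrity rules: unique
#' patient ids, death on or after diagnosis, stage IV if and only if the
#' reference M status is M1 (when both are populated), non-empty code lists,
#' and join-key closure of the claims onto the patients.
#'
#' @param patients Data frame with the columns listed by
#'   [data_dictionary()]`$patient_columns`.
#' @param claims Data frame with the columns listed by
#'   [data_dictionary()]`$claim_columns`.  `codes` is a semicolon-separated
#'   list of diagnosis codes sharing the row's `icd_version` (9 or 10).
#' @param provenance Free-form list recording where the data came from
#'   (file names, simulator seed, ...).
#' @param strict If `TRUE` (default) a claim whose `patient_id` is absent
#'   from the patient table is an error; if `FALSE` such orphan claims are
#'   dropped with a warning.
#' @return An object of class `claims_cohort`: a list with elements
#'   `patients`, `claims`, `provenance`.
#' @export
cohort <- function(patients, claims, provenance = list(), strict = TRUE) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  claims <- as.data.frame(claims, stringsAsFactors = FALSE)

  miss <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(miss)) {
    stop("patients table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(CLAIM_COLUMNS, names(claims))
  if (length(miss)) {
    stop("claims table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  patients <- patients[PATIENT_COLUMNS]
  claims <- claims[CLAIM_COLUMNS]

  patients$patient_id <- as.character(patients$patient_id)
  patients$diagnosis_date <- as_date_strict(patients$diagnosis_date,
                                            "diagnosis_date")
  patients$death_date <- as_date_strict(patients$death_date, "death_date",
                                        allow_na = TRUE)
  patients$resected <- as_logical_strict(patients$resected, "resected")
  for (col in c("reference_m_status", "age_group", "sex", "tumour_location",
                "charlson_category", "t_stage", "n_status", "ajcc_stage")) {
    patients[[col]] <- as.character(patients[[col]])
  }
  check_enum(patients$reference_m_status, M_STATUS_LEVELS,
             "reference_m_status")
  check_enum(patients$age_group, AGE_LEVELS, "age_group")
  check_enum(patients$sex, SEX_LEVELS, "sex")
  check_enum(patients$tumour_location, TUMOUR_LEVELS, "tumour_location")
  check_enum(patients$charlson_category, CHARLSON_LEVELS, "charlson_category")
  check_enum(patients$t_stage, T_LEVELS, "t_stage")
  check_enum(patients$n_status, N_LEVELS, "n_status")
  check_enum(patients$ajcc_stage, AJCC_LEVELS, "ajcc_stage")

  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup)) {
    stop("duplicate patient_id in cohort: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(patients$death_date) &
                 patients$death_date < patients$diagnosis_date)
  if (length(bad)) {
    stop(sprintf("death_date before diagnosis_date for patient %s",
                 patients$patient_id[bad[1]]), call. = FALSE)
  }
  # M1 is defined as stage IV; the two fields must agree when both populated
  stage_pop <- patients$ajcc_stage != "unknown"
  bad <- which(patients$reference_m_status == "M1" & stage_pop &
                 patients$ajcc_stage != "IV")
  if (length(bad)) {
    stop(sprintf("patient %s has reference_m_status M1 but ajcc_stage %s",
                 patients$patient_id[bad[1]], patients$ajcc_stage[bad[1]]),
         call. = FALSE)
  }
  bad <- which(patients$reference_m_status == "M0" &
                 patients$ajcc_stage == "IV")
  if (length(bad)) {
    stop(sprintf("patient %s has ajcc_stage IV but reference_m_status M0",
                 patients$patient_id[bad[1]]), call. = FALSE)
  }

  claims$patient_id <- as.character(claims$patient_id)
  claims$source <- as.character(claims$source)
  check_enum(claims$source, SOURCE_LEVELS, "claim source")
  claims$service_date <- as_date_strict(claims$service_date, "service_date")
  claims$icd_version <- as.integer(claims$icd_version)
  check_enum(claims$icd_version, c(9L, 10L), "icd_version")
  claims$codes <- normalize_codes_cell(claims$codes)
  empty <- which(!nzchar(claims$codes))
  if (length(empty)) {
    stop(sprintf("claim at row %d has no diagnosis codes after normalization",
                 empty[1]), call. = FALSE)
  }

  orphan <- !(claims$patient_id %in% patients$patient_id)
  if (any(orphan)) {
    if (strict) {
      stop(sprintf(
        "%d claim(s) reference patient id(s) absent from the cohort (e.g. %s)",
        sum(orphan), claims$patient_id[which(orphan)[1]]), call. = FALSE)
    }
    warning(sprintf("dropping %d orphan claim(s)", sum(orphan)),
            call. = FALSE)
    claims <- claims[!orphan, , drop = FALSE]
  }

  rownames(patients) <- NULL
  rownames(claims) <- NULL
  structure(list(patients = patients, claims = claims,
                 provenance = provenance),
            class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  st <- table(factor(x$patients$reference_m_status, levels = M_STATUS_LEVELS))
  cat(sprintf("<claims_cohort> %d patients, %d claims\n", n, nrow(x$claims)))
  if (n > 0) {
    cat(sprintf("  reference status: M1 %d (%.1f%%), M0 %d, UNKNOWN %d\n",
                st[["M1"]], 100 * st[["M1"]] / n, st[["M0"]],
                st[["UNKNOWN"]]))
  }
  if (nrow(x$claims) > 0) {
    src <- table(factor(x$claims$source, levels = SOURCE_LEVELS))
    cat(sprintf("  claims by source: hospitalization %d, ED %d, outpatient %d\n",
                src[["HOSPITALIZATION"]], src[["ED"]], src[["OUTPATIENT"]]))
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

read_table_file <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss)) {
    stop(sprintf("file %s missing mandatory column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a linked cohort from delimited text files
#'
#' Reads the patient and claims tables (comma-delimited, UTF-8, header row;
#' see [data_dictionary()]), normalizes diagnosis codes, validates both
#' tables and reports the patient and claim counts.
#'
#' @inheritParams cohort
#' @param patient_path,claims_path Paths to the two CSV files.
#' @return A [cohort()] object.
#' @export
read_cohort <- function(patient_path, claims_path, strict = TRUE) {
  pat <- read_table_file(patient_path, PATIENT_COLUMNS)
  clm <- read_table_file(claims_path, CLAIM_COLUMNS)
  co <- cohort(pat, clm,
               provenance = list(patient_file = patient_path,
                                 claims_file = claims_path),
               strict = strict)
  message(sprintf("read %d patients and %d claims",
                  nrow(co$patients), nrow(co$claims)))
  co
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: the written files re-read to a cohort equal
#' field-for-field to the input.  Dates are ISO-8601; an absent death date is
#' an empty cell; `UNKNOWN` reference status is written as the literal token.
#'
#' @param x A [cohort()] object.
#' @param patient_path,claims_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_cohort <- function(x, patient_path, claims_path) {
  stopifnot(inherits(x, "claims_cohort"))
  pat <- x$patients
  pat$diagnosis_date <- format(pat$diagnosis_date, "%Y-%m-%d")
  pat$death_date <- ifelse(is.na(pat$death_date), "",
                           format(pat$death_date, "%Y-%m-%d"))
  pat$resected <- ifelse(pat$resected, "true", "false")
  clm <- x$claims
  clm$service_date <- format(clm$service_date, "%Y-%m-%d")
  utils::write.csv(pat, patient_path, row.names = FALSE, quote = TRUE,
                   na = "")
  utils::write.csv(clm, claims_path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(x)
}

#' Restrict a cohort to surgically resected patients
#'
#' Sub-cohort of patients with `resected = TRUE` and only their claims; used
#' for the sensitivity analysis on the resection subgroup, whose chart
#' staging is of higher quality.  Applying it twice equals applying it once.
#'
#' @param x A [cohort()] object with `resected` populated for every patient.
#' @return A [cohort()] object (possibly empty).
#' @export
restrict_to_resection <- function(x) {
  stopifnot(inherits(x, "claims_cohort"))
  if (anyNA(x$patients$resected)) {
    stop("resected must be populated for every patient", call. = FALSE)
  }
  keep <- x$patients$resected
  ids <- x$patients$patient_id[keep]
  cohort(x$patients[keep, , drop = FALSE],
         x$claims[x$claims$patient_id %in% ids, , drop = FALSE],
         provenance = c(x$provenance, list(restricted_to_resection = TRUE)))
}
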