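# Fixed token spellings for every categorical field in the patient and claims
# tables.  These are the only spellings the readers accept and the writers emit.

SOURCE_LEVELS   <- c("HOSPITALIZATION", "ED", "OUTPATIENT")
M_STATUS_LEVELS <- c("M1", "M0", "UNKNOWN")
AGE_LEVELS      <- c("<50", "50-54", "55-59", "60-64", "65-69", "70+")
SEX_LEVELS      <- c("F", "M")
TUMOUR_LEVELS   <- c("distal", "entire", "GEJ", "middle", "proximal", "unknown")
CHARLSON_LEVELS <- c("no_prev_hosp", "0", "1", "2+")
T_LEVELS        <- c("Tis/T0/T1", "T2", "T3", "T4A", "T4B", "TX")
N_LEVELS        <- c("N0", "N1", "N2", "N3A", "N3B", "NX")
AJCC_LEVELS     <- c("0/IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV",
                     "unknown")

TIER_LEVELS   <- c("CONSERVATIVE", "LESS_CONSERVATIVE", "INCLUSIVE")
RULE_LEVELS   <- c("H1", "H1_OR_O2", "H1_OR_O1")
WINDOW_LEVELS <- c("PRE90_POST90", "PRE180_POST180", "PRE90_NOLIMIT")
ED_LEVELS     <- c("ED_AS_OUTPATIENT", "ED_IGNORED")

PATIENT_COLUMNS <- c("patient_id", "diagnosis_date", "reference_m_status",
                     "death_date", "age_group", "sex", "tumour_location",
                     "charlson_category", "t_stage", "n_status", "ajcc_stage",
                     "resected")
CLAIM_COLUMNS <- c("patient_id", "source", "service_date", "icd_version",
                   "codes")

#' Data dictionary for cohort and claims tables
#'
#' Returns the column names and the fixed enum token spellings used by
#' [read_cohort()] and [write_cohort()].  Dates are ISO-8601 calendar dates
#' (`YYYY-MM-DD`); an empty `death_date` cell means the patient is not known
#' to have died; `resected` is serialized as `true`/`false`; the `codes` cell
#' of the claims table is a semicolon-separated list of diagnosis codes, all
#' sharing the row's `icd_version`.
#'
#' @return A named list with elements `patient_columns`, `claim_columns` and
#'   one character vector of allowed tokens per categorical field.
#' @export
#' @examples
#' data_dictionary()$source
data_dictionary <- function() {
  list(
    patient_columns    = PATIENT_COLUMNS,
    claim_columns      = CLAIM_COLUMNS,
    reference_m_status = M_STATUS_LEVELS,
    source             = SOURCE_LEVELS,
    age_group          = AGE_LEVELS,
    sex                = SEX_LEVELS,
    tumour_location    = TUMOUR_LEVELS,
    charlson_category  = CHARLSON_LEVELS,
    t_stage            = T_LEVELS,
    n_status           = N_LEVELS,
    ajcc_stage         = AJCC_LEVELS,
    tier               = TIER_LEVELS,
    source_rule        = RULE_LEVELS,
    window             = WINDOW_LEVELS,
    ed_policy          = ED_LEVELS
  )
}
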