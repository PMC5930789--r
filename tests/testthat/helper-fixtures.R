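# fixture builders and independent reference implementations

make_patients <- function(n,
                          patient_id = sprintf("P%03d", seq_len(n)),
                          diagnosis_date = as.Date("2006-06-01"),
                          reference_m_status = "M0",
                          death_date = as.Date(NA),
                          age_group = "70+", sex = "F",
                          tumour_location = "distal",
                          charlson_category = "0",
                          t_stage = "T3", n_status = "N0",
                          ajcc_stage = NULL, resected = FALSE) {
  status <- rep_len(reference_m_status, n)
  if (is.null(ajcc_stage)) {
    ajcc_stage <- ifelse(status == "M1", "IV", "unknown")
  }
  data.frame(patient_id = patient_id,
             diagnosis_date = rep_len(diagnosis_date, n),
             reference_m_status = status,
             death_date = rep_len(death_date, n),
             age_group = rep_len(age_group, n), sex = rep_len(sex, n),
             tumour_location = rep_len(tumour_location, n),
             charlson_category = rep_len(charlson_category, n),
             t_stage = rep_len(t_stage, n), n_status = rep_len(n_status, n),
             ajcc_stage = rep_len(ajcc_stage, n),
             resected = rep_len(resected, n),
             stringsAsFactors = FALSE)
}

make_claims <- function(patient_id, source = "HOSPITALIZATION",
                        service_date = as.Date("2006-06-01"),
                        icd_version = 10L, codes = "C787") {
  n <- max(length(patient_id), length(source), length(service_date),
           length(codes))
  data.frame(patient_id = rep_len(patient_id, n),
             source = rep_len(source, n),
             service_date = rep_len(service_date, n),
             icd_version = rep_len(icd_version, n),
             codes = rep_len(codes, n), stringsAsFactors = FALSE)
}

empty_claims <- function() {
  data.frame(patient_id = character(), source = character(),
             service_date = as.Date(character()), icd_version = integer(),
             codes = character(), stringsAsFactors = FALSE)
}

# messy random cohorts for engine-vs-brute-force equivalence: claims far
# outside every window, mixed ICD versions, duplicate dates, multi-code
# cells, zero-claim patients
random_small_cohort <- function(n_max = 50) {
  n <- sample.int(n_max, 1)
  diag <- as.Date("2006-01-01") + sample.int(700, n, replace = TRUE)
  status <- sample(c("M1", "M0", "UNKNOWN"), n, replace = TRUE,
                   prob = c(0.5, 0.4, 0.1))
  pats <- make_patients(n, diagnosis_date = diag,
                        reference_m_status = status,
                        resected = sample(c(TRUE, FALSE), n, replace = TRUE))
  pool9 <- c("1960", "196", "197", "1988", "195", "199", "1991", "174",
             "1539", "E11", "401", "535", "789")
  pool10 <- c("C779", "C787", "C795", "C80", "C768", "C509", "C169",
              "C159", "C229", "E119", "K219", "I10")
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(sample(0:6, 1))) {
      v <- sample(c(9L, 10L), 1)
      pool <- if (v == 9) pool9 else pool10
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pats$patient_id[i],
        source = sample(SOURCE_LEVELS <- c("HOSPITALIZATION", "ED",
                                           "OUTPATIENT"), 1),
        service_date = diag[i] + sample(-400:400, 1),
        icd_version = v,
        codes = paste(sample(pool, sample(1:3, 1), replace = TRUE),
                      collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  claims <- if (length(rows)) do.call(rbind, rows) else empty_claims()
  cohort(pats, claims)
}

# prefix-expansion oracle for code matching: expands every pattern to its
# explicit code set over a finite universe, then tests set membership
brute_code_set <- function(lst, universe, version) {
  acc <- character()
  pat <- lst$patterns
  for (i in seq_len(nrow(pat))) {
    if (pat$icd_version[i] != version) next
    pre <- pat$prefix[i]
    m <- universe[substr(universe, 1, nchar(pre)) == pre]
    if (nzchar(pat$exclusions[i])) {
      for (e in strsplit(pat$exclusions[i], ";", fixed = TRUE)[[1]]) {
        m <- m[substr(m, 1, nchar(e)) != e]
      }
    }
    acc <- union(acc, m)
  }
  acc
}

icd9_universe <- function() {
  c(sprintf("%03d", 0:999), sprintf("%04d", 0:9999))
}

icd10_universe <- function() {
  three <- paste0("C", sprintf("%02d", 0:99))
  c(three, paste0(rep(three, each = 10), 0:9))
}

# naive double-loop reference classifier, independent of the data.table
# engine: regex prefix matching, explicit window bounds, per-patient loops
brute_classify <- function(co, config, codelists = default_codelists()) {
  lst <- if (inherits(codelists, "code_list")) codelists else
    codelists[[config$tier]]
  qualifies <- function(codes_cell, version) {
    for (code in strsplit(codes_cell, ";", fixed = TRUE)[[1]]) {
      for (i in seq_len(nrow(lst$patterns))) {
        p <- lst$patterns[i, ]
        if (p$icd_version != version) next
        if (!grepl(paste0("^", p$prefix), code)) next
        excluded <- FALSE
        if (nzchar(p$exclusions)) {
          for (e in strsplit(p$exclusions, ";", fixed = TRUE)[[1]]) {
            if (grepl(paste0("^", e), code)) excluded <- TRUE
          }
        }
        if (!excluded) return(TRUE)
      }
    }
    FALSE
  }
  out <- NULL
  for (i in seq_len(nrow(co$patients))) {
    p <- co$patients[i, ]
    wb <- window_bounds(p$diagnosis_date, config$window)
    cl <- co$claims[co$claims$patient_id == p$patient_id, , drop = FALSE]
    n_hosp <- 0L
    out_dates <- as.Date(character())
    out_rows <- 0L
    for (j in seq_len(nrow(cl))) {
      r <- cl[j, ]
      if (r$service_date < wb$start) next
      if (!is.na(wb$end) && r$service_date > wb$end) next
      if (!qualifies(r$codes, r$icd_version)) next
      if (r$source == "HOSPITALIZATION") {
        n_hosp <- n_hosp + 1L
      } else if (r$source == "OUTPATIENT" ||
                 (r$source == "ED" &&
                  config$ed_policy == "ED_AS_OUTPATIENT")) {
        out_dates <- c(out_dates, r$service_date)
        out_rows <- out_rows + 1L
      }
    }
    n_out <- if (config$outpatient_units == "distinct_dates") {
      length(unique(out_dates))
    } else {
      out_rows
    }
    pos <- switch(config$source_rule,
                  H1 = n_hosp >= 1,
                  H1_OR_O2 = n_hosp >= 1 || n_out >= 2,
                  H1_OR_O1 = n_hosp >= 1 || n_out >= 1)
    out <- rbind(out, data.frame(
      patient_id = p$patient_id,
      predicted_m = if (pos) "POSITIVE" else "NEGATIVE",
      n_hosp_qualifying = n_hosp,
      n_outpatient_dates_qualifying = n_out,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
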