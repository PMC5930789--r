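#' Published cohort margins of the original validation cohort
#'
#' Descriptive margins of the population-based Ontario gastric cancer
#' cohort (diagnoses 2005-2008, chart-review reference standard) on which
#' the 27 case-finding algorithms were originally validated: patient counts
#' by reference M status and, per status class, the percentage distribution
#' of age group, sex, tumour location and Charlson category, plus one- and
#' five-year mortality.  Shipped as a plain-text table; used to parameterize
#' the `published` simulation profile and for reference arithmetic.
#'
#' @return Data frame with columns `block`, `level`, `m1`, `m0`.  The
#'   `block = "n"` row holds patient counts; all other rows are percentages
#'   as originally printed.
#' @export
reference_cohort_margins <- function() {
  utils::read.csv(system.file("extdata", "reference_cohort_margins.csv",
                              package = "m1claims"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published operating characteristics of the 27 algorithms
#'
#' Sensitivity, specificity, PPV, NPV and accuracy (percentages, with
#' bootstrapped 95% confidence limits) reported for each of the 27
#' case-finding algorithms in the original validation cohort.  Row order
#' and numbering follow [enumerate_algorithms()].  One upper confidence
#' limit (algorithm 13 sensitivity) was not legible in the source table and
#' is stored as `NA`.  These values are the default calibration targets of
#' [calibrate_params()].
#'
#' @return Data frame with columns `algorithm_number`, `window`, `tier`,
#'   `source_rule`, and `se`, `se_lo`, `se_hi`, ..., `a`, `a_lo`, `a_hi`
#'   (percentages).
#' @export
reference_performance <- function() {
  utils::read.csv(system.file("extdata",
                              "reference_algorithm_performance.csv",
                              package = "m1claims"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
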