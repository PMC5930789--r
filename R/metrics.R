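METRIC_LEVELS <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")

#' Cross-tabulate predictions against the reference standard
#'
#' Builds the 2x2 confusion table of predicted M status against chart-review
#' reference status.  Patients with `UNKNOWN` reference status are handled
#' by policy: `AS_M0` (default) counts them in the M0 row, matching the
#' reference-standard rule that a record with no evidence of metastasis is
#' M0; `EXCLUDE` drops them and reports how many were dropped (the
#' unknown-status sensitivity analysis).
#'
#' @param predictions Data frame from [classify_cohort()] (one row per
#'   patient; a missing prediction is an error).
#' @param x A [cohort()] object.
#' @param unknown_policy `"AS_M0"` or `"EXCLUDE"`.
#' @return Object of class `confusion_table`: list with integer fields `tp`,
#'   `fp`, `fn`, `tn`, `n_excluded_unknown` and the policy used.
#' @export
confusion <- function(predictions, x, unknown_policy = c("AS_M0", "EXCLUDE")) {
  stopifnot(inherits(x, "claims_cohort"))
  unknown_policy <- match.arg(unknown_policy)
  idx <- match(x$patients$patient_id, predictions$patient_id)
  if (anyNA(idx)) {
    stop(sprintf("missing prediction for patient %s",
                 x$patients$patient_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  pred <- predictions$predicted_m[idx]
  check_enum(pred, c("POSITIVE", "NEGATIVE"), "predicted_m")
  ref <- x$patients$reference_m_status
  n_excl <- 0L
  if (unknown_policy == "EXCLUDE") {
    drop <- ref == "UNKNOWN"
    n_excl <- sum(drop)
    pred <- pred[!drop]
    ref <- ref[!drop]
  } else {
    ref[ref == "UNKNOWN"] <- "M0"
  }
  structure(list(
    tp = sum(pred == "POSITIVE" & ref == "M1"),
    fp = sum(pred == "POSITIVE" & ref == "M0"),
    fn = sum(pred == "NEGATIVE" & ref == "M1"),
    tn = sum(pred == "NEGATIVE" & ref == "M0"),
    n_excluded_unknown = n_excl,
    unknown_policy = unknown_policy), class = "confusion_table")
}

#' Build a confusion table from cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param n_excluded_unknown Patients excluded under the `EXCLUDE` policy.
#' @param unknown_policy Policy label.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn, n_excluded_unknown = 0L,
                            unknown_policy = "AS_M0") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn, ex = n_excluded_unknown)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  if (unknown_policy == "AS_M0" && n_excluded_unknown != 0) {
    stop("under AS_M0 no patients are excluded", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_excluded_unknown = as.integer(n_excluded_unknown),
                 unknown_policy = unknown_policy),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP=%d FP=%d FN=%d TN=%d (excluded unknown: %d, policy %s)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_excluded_unknown,
              x$unknown_policy))
  invisible(x)
}

#' Diagnostic accuracy metrics from a confusion table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`.  A metric whose denominator is zero is
#' *undefined* and returned as `NA`, never silently 0.
#'
#' @param ct A `confusion_table`.
#' @return Named numeric vector of the five metrics as proportions in
#'   `[0, 1]` (`NA` where undefined).
#' @export
#' @examples
#' diagnostic_metrics(confusion_table(tp = 50, fp = 10, fn = 50, tn = 90))
diagnostic_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = sdiv(ct$tp, ct$tp + ct$fn),
    specificity = sdiv(ct$tn, ct$tn + ct$fp),
    ppv = sdiv(ct$tp, ct$tp + ct$fp),
    npv = sdiv(ct$tn, ct$tn + ct$fn),
    accuracy = sdiv(ct$tp + ct$tn, ct$tp + ct$fp + ct$fn + ct$tn))
}

# Patient-level bootstrap of a confusion table.  Classification is
# deterministic per patient, so resampling patients with replacement is
# distributionally identical to drawing the four (five, with exclusions)
# cell counts from a multinomial over the observed cell proportions; that
# equivalence is what makes B = 5000 replicates cheap.  Returns a 5 x B
# matrix of cell counts (tp, fp, fn, tn, excluded).
boot_cells <- function(ct, n_bootstrap) {
  counts <- c(ct$tp, ct$fp, ct$fn, ct$tn, ct$n_excluded_unknown)
  n <- sum(counts)
  if (n == 0) stop("cannot bootstrap an empty confusion table", call. = FALSE)
  stats::rmultinom(n_bootstrap, size = n, prob = counts / n)
}

metric_from_cells <- function(cells, metric) {
  tp <- cells[1, ]; fp <- cells[2, ]; fn <- cells[3, ]; tn <- cells[4, ]
  num <- switch(metric, sensitivity = tp, specificity = tn, ppv = tp,
                npv = tn, accuracy = tp + tn)
  den <- switch(metric, sensitivity = tp + fn, specificity = tn + fp,
                ppv = tp + fp, npv = tn + fn, accuracy = tp + fp + fn + tn)
  ifelse(den > 0, num / den, NA_real_)
}

percentile_interval <- function(reps, ci_level, undefined = "drop") {
  nd <- sum(is.na(reps))
  if (undefined == "propagate" && nd > 0) {
    return(list(low = NA_real_, high = NA_real_, n_undefined = nd))
  }
  ok <- reps[!is.na(reps)]
  if (!length(ok)) {
    stop("all bootstrap replicates undefined for this metric", call. = FALSE)
  }
  alpha <- (1 - ci_level) / 2
  q <- quantile_type1(ok, c(alpha, 1 - alpha))
  list(low = q[1], high = q[2], n_undefined = nd)
}

#' Percentile-bootstrap confidence interval for one accuracy metric
#'
#' Classifies the cohort under `config`, cross-tabulates against the
#' reference standard, resamples patients with replacement `n_bootstrap`
#' times, recomputes the metric in each replicate and returns the
#' `(1-level)/2` and `1-(1-level)/2` nearest-rank percentiles of the defined
#' replicate values.  Replicates where the metric's denominator is zero are
#' dropped from the percentile computation and counted
#' (`undefined = "drop"`, the default) or propagated as an undefined CI
#' (`"propagate"`).  Deterministic given `seed`.
#'
#' @inheritParams classify_cohort
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"accuracy"`.
#' @param n_bootstrap Number of bootstrap replicates (default 5000).
#' @param seed Integer RNG seed.
#' @param ci_level Confidence level (default 0.95).
#' @param unknown_policy Passed to [confusion()].
#' @param undefined `"drop"` or `"propagate"`.
#' @return Object of class `metric_estimate`: list with `metric`, `point`,
#'   `ci_low`, `ci_high`, `n_bootstrap`, `n_undefined`, `seed`, `ci_level`.
#' @export
bootstrap_ci <- function(x, config, metric, n_bootstrap = 5000, seed = 1L,
                         ci_level = 0.95, codelists = default_codelists(),
                         unknown_policy = "AS_M0",
                         undefined = c("drop", "propagate")) {
  metric <- match.arg(metric, METRIC_LEVELS)
  undefined <- match.arg(undefined)
  if (nrow(x$patients) == 0) stop("empty cohort", call. = FALSE)
  pred <- classify_cohort(x, config, codelists)
  ct <- confusion(pred, x, unknown_policy)
  point <- diagnostic_metrics(ct)[[metric]]
  set.seed(as.integer(seed))
  reps <- metric_from_cells(boot_cells(ct, n_bootstrap), metric)
  pi <- percentile_interval(reps, ci_level, undefined)
  structure(list(metric = metric, point = point, ci_low = pi$low,
                 ci_high = pi$high, n_bootstrap = as.integer(n_bootstrap),
                 n_undefined = pi$n_undefined, seed = as.integer(seed),
                 ci_level = ci_level),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("<metric_estimate> %s = %s, %g%% CI [%s, %s] (B=%d, %d undefined, seed=%d)\n",
              x$metric,
              ifelse(is.na(x$point), "undefined", sprintf("%.4f", x$point)),
              100 * x$ci_level,
              ifelse(is.na(x$ci_low), "NA", sprintf("%.4f", x$ci_low)),
              ifelse(is.na(x$ci_high), "NA", sprintf("%.4f", x$ci_high)),
              x$n_bootstrap, x$n_undefined, x$seed))
  invisible(x)
}

#' Evaluate a set of algorithms on a cohort
#'
#' One row per algorithm, in the supplied order: the five accuracy metrics
#' with percentile-bootstrap confidence limits.  The RNG is seeded once with
#' `seed`, so the whole report is deterministic.
#'
#' @inheritParams bootstrap_ci
#' @param configs List of [algorithm_config()]s; defaults to all 27 via
#'   [enumerate_algorithms()].
#' @return Data frame of class `algorithm_report` with columns
#'   `algorithm_number`, `window`, `tier`, `source_rule`, `n`,
#'   `n_excluded_unknown`, and for each metric `m` the columns `m`, `m_lo`,
#'   `m_hi` (proportions).  Attributes record seed, replicate count, CI
#'   level and code-list provenance.
#' @export
evaluate_all <- function(x, configs = enumerate_algorithms(),
                         n_bootstrap = 5000, seed = 1L, ci_level = 0.95,
                         codelists = default_codelists(),
                         unknown_policy = "AS_M0",
                         undefined = c("drop", "propagate")) {
  stopifnot(length(configs) >= 1)
  undefined <- match.arg(undefined)
  set.seed(as.integer(seed))
  short <- c(sensitivity = "se", specificity = "sp", ppv = "ppv",
             npv = "npv", accuracy = "a")
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    pred <- classify_cohort(x, cfg, codelists)
    ct <- confusion(pred, x, unknown_policy)
    pm <- diagnostic_metrics(ct)
    cells <- boot_cells(ct, n_bootstrap)
    row <- data.frame(
      algorithm_number = if (is.null(cfg$algorithm_number)) NA_integer_ else
        cfg$algorithm_number,
      window = cfg$window, tier = cfg$tier, source_rule = cfg$source_rule,
      n = ct$tp + ct$fp + ct$fn + ct$tn,
      n_excluded_unknown = ct$n_excluded_unknown,
      stringsAsFactors = FALSE)
    for (m in METRIC_LEVELS) {
      pi <- percentile_interval(metric_from_cells(cells, m), ci_level,
                                undefined)
      row[[short[[m]]]] <- pm[[m]]
      row[[paste0(short[[m]], "_lo")]] <- pi$low
      row[[paste0(short[[m]], "_hi")]] <- pi$high
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  prov <- if (inherits(codelists, "code_list")) codelists$provenance else
    unique(vapply(codelists, `[[`, character(1), "provenance"))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_bootstrap") <- as.integer(n_bootstrap)
  attr(out, "ci_level") <- ci_level
  attr(out, "codelist_provenance") <- prov
  class(out) <- c("algorithm_report", class(out))
  out
}

death_within <- function(x, days) {
  !is.na(x$patients$death_date) &
    x$patients$death_date <= x$patients$diagnosis_date + days
}

assign_cells <- function(predictions, x, unknown_policy) {
  idx <- match(x$patients$patient_id, predictions$patient_id)
  if (anyNA(idx)) stop("predictions must cover every patient", call. = FALSE)
  pred <- predictions$predicted_m[idx]
  ref <- x$patients$reference_m_status
  cell <- rep(NA_character_, length(ref))
  if (unknown_policy == "AS_M0") ref[ref == "UNKNOWN"] <- "M0"
  cell[pred == "POSITIVE" & ref == "M1"] <- "TP"
  cell[pred == "POSITIVE" & ref == "M0"] <- "FP"
  cell[pred == "NEGATIVE" & ref == "M1"] <- "FN"
  cell[pred == "NEGATIVE" & ref == "M0"] <- "TN"
  cell   # NA = excluded unknown
}

PROFILE_COVARIATES <- list(age_group = quote(AGE_LEVELS),
                           sex = quote(SEX_LEVELS),
                           tumour_location = quote(TUMOUR_LEVELS),
                           charlson_category = quote(CHARLSON_LEVELS),
                           t_stage = quote(T_LEVELS),
                           n_status = quote(N_LEVELS),
                           ajcc_stage = quote(AJCC_LEVELS))

#' Describe concordant and discordant classifications
#'
#' For each cell of the confusion table (TP, FP, FN, TN): the percentage
#' distribution of every descriptive covariate (age group, sex, tumour
#' location, Charlson category, T stage, N status, AJCC stage), computed
#' over that cell's patients only, plus the percentage dead within 1 year
#' (365 days) and 5 years (1826 days) of diagnosis.  Empty cells are
#' reported with `n = 0` and no percentage rows.
#'
#' @inheritParams confusion
#' @return Object of class `cell_profiles`: list with `n` (named cell
#'   counts) and `profile`, a long data frame with columns `cell`,
#'   `variable`, `level`, `percent`.
#' @export
describe_cells <- function(predictions, x,
                           unknown_policy = c("AS_M0", "EXCLUDE")) {
  unknown_policy <- match.arg(unknown_policy)
  cell <- assign_cells(predictions, x, unknown_policy)
  cells <- c("TP", "FP", "FN", "TN")
  n <- vapply(cells, function(cc) sum(cell == cc, na.rm = TRUE), integer(1))
  rows <- list()
  for (cc in cells) {
    sel <- which(!is.na(cell) & cell == cc)
    if (!length(sel)) next
    for (v in names(PROFILE_COVARIATES)) {
      lv <- eval(PROFILE_COVARIATES[[v]])
      tab <- table(factor(x$patients[[v]][sel], levels = lv))
      rows[[length(rows) + 1]] <- data.frame(
        cell = cc, variable = v, level = lv,
        percent = 100 * as.numeric(tab) / length(sel),
        stringsAsFactors = FALSE)
    }
    for (k in c(1, 5)) {
      dead <- death_within(x, if (k == 1) 365 else 1826)[sel]
      rows[[length(rows) + 1]] <- data.frame(
        cell = cc, variable = sprintf("death_within_%dy", k), level = "",
        percent = 100 * mean(dead), stringsAsFactors = FALSE)
    }
  }
  profile <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(), variable = character(),
               level = character(), percent = numeric(),
               stringsAsFactors = FALSE)
  structure(list(n = n, profile = profile), class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("<cell_profiles> n:",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = " "), "\n")
  empty <- names(x$n)[x$n == 0]
  if (length(empty)) cat("  empty cell(s):", paste(empty, collapse = ", "), "\n")
  invisible(x)
}

#' Content validity: one-year mortality of concordant vs discordant groups
#'
#' Metastatic gastric cancer carries much higher short-term mortality than
#' non-metastatic disease, so patients the algorithm classifies *correctly*
#' as metastatic (TP) should die within a year more often than those
#' incorrectly flagged (FP).  Reports the 1-year mortality percentage of
#' each confusion cell, paired by reference class (TP vs FN among reference
#' M1; TN vs FP among reference M0).  No hypothesis test is attached.
#'
#' @inheritParams confusion
#' @return Data frame of class `content_validity` with columns `cell`,
#'   `reference`, `algorithm`, `n`, `deaths_1y`, `death_1y_pct` (`NaN` for
#'   empty cells).
#' @export
content_validity <- function(predictions, x,
                             unknown_policy = c("AS_M0", "EXCLUDE")) {
  unknown_policy <- match.arg(unknown_policy)
  cell <- assign_cells(predictions, x, unknown_policy)
  dead1 <- death_within(x, 365)
  out <- do.call(rbind, lapply(c("TP", "FP", "FN", "TN"), function(cc) {
    sel <- which(!is.na(cell) & cell == cc)
    data.frame(cell = cc,
               reference = if (cc %in% c("TP", "FN")) "M1" else "M0",
               algorithm = if (cc %in% c("TP", "FP")) "POSITIVE" else
                 "NEGATIVE",
               n = length(sel), deaths_1y = sum(dead1[sel]),
               death_1y_pct = 100 * mean(dead1[sel]),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("content_validity", class(out))
  out
}
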