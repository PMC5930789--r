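test_that("confusion cross-tabulation matches hand tallies and handles UNKNOWN by policy", {
  status <- rep(c("M1", "M0"), c(6, 4))
  co <- cohort(make_patients(10, reference_m_status = status),
               empty_claims())
  perfect <- data.frame(patient_id = co$patients$patient_id,
                        predicted_m = ifelse(status == "M1", "POSITIVE",
                                             "NEGATIVE"))
  ct <- confusion(perfect, co)
  expect_equal(ct[c("tp", "fp", "fn", "tn")],
               list(tp = 6L, fp = 0L, fn = 0L, tn = 4L))

  all_pos <- data.frame(patient_id = co$patients$patient_id,
                        predicted_m = "POSITIVE")
  ct <- confusion(all_pos, co)
  expect_equal(ct[c("tp", "fp", "fn", "tn")],
               list(tp = 6L, fp = 4L, fn = 0L, tn = 0L))

  # 20-patient hand-built cross-tabulation: 12 M1 of which 9 flagged,
  # 8 M0 of which 2 flagged
  status <- rep(c("M1", "M0"), c(12, 8))
  co <- cohort(make_patients(20, reference_m_status = status),
               empty_claims())
  pred <- data.frame(patient_id = co$patients$patient_id,
                     predicted_m = c(rep("POSITIVE", 9), rep("NEGATIVE", 3),
                                     rep("POSITIVE", 2), rep("NEGATIVE", 6)))
  ct <- confusion(pred, co)
  expect_equal(ct[c("tp", "fp", "fn", "tn")],
               list(tp = 9L, fp = 2L, fn = 3L, tn = 6L))

  expect_error(confusion(pred[-1, ], co), "missing prediction")

  # UNKNOWN: counted with M0 by default, dropped under EXCLUDE
  status <- c("M1", "M0", "UNKNOWN", "UNKNOWN")
  co <- cohort(make_patients(4, reference_m_status = status),
               empty_claims())
  pred <- data.frame(patient_id = co$patients$patient_id,
                     predicted_m = c("POSITIVE", "NEGATIVE", "POSITIVE",
                                     "NEGATIVE"))
  as_m0 <- confusion(pred, co, "AS_M0")
  expect_equal(as_m0[c("tp", "fp", "fn", "tn", "n_excluded_unknown")],
               list(tp = 1L, fp = 1L, fn = 0L, tn = 2L,
                    n_excluded_unknown = 0L))
  excl <- confusion(pred, co, "EXCLUDE")
  expect_equal(excl[c("tp", "fp", "fn", "tn", "n_excluded_unknown")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L,
                    n_excluded_unknown = 2L))
})

test_that("the two unknown policies agree exactly when no UNKNOWN patients exist", {
  set.seed(5)
  for (i in 1:5) {
    co <- random_small_cohort()
    co$patients$reference_m_status[
      co$patients$reference_m_status == "UNKNOWN"] <- "M0"
    pred <- classify_cohort(co, algorithm_from_number(9))
    a <- confusion(pred, co, "AS_M0")
    b <- confusion(pred, co, "EXCLUDE")
    expect_equal(a[c("tp", "fp", "fn", "tn")], b[c("tp", "fp", "fn", "tn")])
  }
})

test_that("diagnostic metrics follow their defining ratios, with NA for zero denominators", {
  m <- diagnostic_metrics(confusion_table(tp = 50, fp = 10, fn = 50,
                                          tn = 90))
  expect_equal(m[["sensitivity"]], 0.5)
  expect_equal(m[["specificity"]], 0.9)
  expect_equal(m[["ppv"]], 50 / 60)
  expect_equal(m[["npv"]], 90 / 140)
  expect_equal(m[["accuracy"]], 0.7)

  expect_true(all(diagnostic_metrics(
    confusion_table(tp = 1, fp = 0, fn = 0, tn = 1)) == 1))

  m <- diagnostic_metrics(confusion_table(tp = 0, fp = 0, fn = 3, tn = 2))
  expect_true(is.na(m[["ppv"]]))
  expect_equal(m[["sensitivity"]], 0)
  m <- diagnostic_metrics(confusion_table(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(all(is.na(m)))
})

test_that("metric identities and Bayes consistency hold on random tables", {
  set.seed(12)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(2, 20, 200), 1))
    ct <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    m <- diagnostic_metrics(ct)
    tot <- sum(cells)
    if (tot > 0 && !is.na(m[["accuracy"]])) {
      expect_equal(m[["accuracy"]] * tot, ct$tp + ct$tn, tolerance = 1e-12)
    }
    if (!is.na(m[["sensitivity"]])) {
      expect_equal(m[["sensitivity"]] * (ct$tp + ct$fn), ct$tp,
                   tolerance = 1e-12)
    }
    if (!anyNA(m[c("sensitivity", "specificity", "ppv")]) && tot > 0) {
      pi <- (ct$tp + ct$fn) / tot
      bayes <- m[["sensitivity"]] * pi /
        (m[["sensitivity"]] * pi + (1 - m[["specificity"]]) * (1 - pi))
      expect_equal(m[["ppv"]], bayes, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap CIs are deterministic given the seed and degenerate for pure cohorts", {
  co <- simulate_cohort(simulation_params(n_patients = 120, seed = 2))
  cfg <- algorithm_from_number(12)
  a <- bootstrap_ci(co, cfg, "sensitivity", n_bootstrap = 300, seed = 17)
  b <- bootstrap_ci(co, cfg, "sensitivity", n_bootstrap = 300, seed = 17)
  expect_identical(a, b)
  c2 <- bootstrap_ci(co, cfg, "sensitivity", n_bootstrap = 300, seed = 18)
  expect_false(identical(a$ci_low, c2$ci_low) &&
                 identical(a$ci_high, c2$ci_high))

  # a cohort of identical all-TP patients has a point-mass bootstrap
  pats <- make_patients(8, reference_m_status = "M1")
  clms <- make_claims(pats$patient_id)
  pure <- cohort(pats, clms)
  est <- bootstrap_ci(pure, cfg, "sensitivity", n_bootstrap = 200, seed = 1)
  expect_equal(est$ci_low, 1)
  expect_equal(est$ci_high, 1)
})

test_that("undefined bootstrap replicates are counted when dropped, or propagated", {
  # tiny cohort with a single M0 patient: many resamples lose the M0 class
  status <- c("M1", "M1", "M0")
  co <- cohort(make_patients(3, reference_m_status = status),
               make_claims(c("P001", "P002")))
  cfg <- algorithm_from_number(1)
  est <- bootstrap_ci(co, cfg, "specificity", n_bootstrap = 400, seed = 4)
  expect_gt(est$n_undefined, 0)
  expect_true(!is.na(est$ci_low) && !is.na(est$ci_high))
  prop <- bootstrap_ci(co, cfg, "specificity", n_bootstrap = 400, seed = 4,
                       undefined = "propagate")
  expect_true(is.na(prop$ci_low) && is.na(prop$ci_high))
})

test_that("bootstrap CI endpoints are order statistics and narrow as the cohort grows", {
  widths <- sapply(c(200, 2000), function(n) {
    co <- simulate_cohort(simulation_params(n_patients = n, seed = 8))
    est <- bootstrap_ci(co, algorithm_from_number(12), "sensitivity",
                        n_bootstrap = 400, seed = 3)
    # endpoints must be achievable sensitivities of integer cell counts
    expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
    est$ci_high - est$ci_low
  })
  expect_lt(widths[2], widths[1])
})

test_that("evaluate_all produces one fully-populated row per algorithm", {
  co <- simulate_cohort(simulation_params(n_patients = 250, seed = 6))
  rep <- evaluate_all(co, n_bootstrap = 100, seed = 5)
  expect_equal(nrow(rep), 27)
  expect_equal(rep$algorithm_number, 1:27)
  for (m in c("se", "sp", "ppv", "npv", "a")) {
    expect_true(all(rep[[paste0(m, "_lo")]] <= rep[[m]] + 1e-12))
    expect_true(all(rep[[paste0(m, "_hi")]] >= rep[[m]] - 1e-12))
  }
  # within each window x tier block, sensitivity is non-decreasing and
  # specificity non-increasing from H1 to H1_OR_O2 to H1_OR_O1
  for (b in seq(1, 25, by = 3)) {
    expect_true(all(diff(rep$se[b:(b + 2)]) >= 0))
    expect_true(all(diff(rep$sp[b:(b + 2)]) <= 0))
  }
})

test_that("cell profiles match hand-computed percentages and flag empty cells", {
  # 40 patients: 24 M1 (18 flagged), 16 M0 (4 flagged)
  status <- rep(c("M1", "M0"), c(24, 16))
  sex <- c(rep(c("F", "M"), c(12, 12)), rep(c("F", "M"), c(10, 6)))
  death <- as.Date(rep(NA, 40))
  death[1:12] <- as.Date("2006-06-01") + 100   # 12 TP die within a year
  death[25:26] <- as.Date("2006-06-01") + 400  # 2 FP die later
  pats <- make_patients(40, reference_m_status = status, sex = sex,
                        death_date = death)
  co <- cohort(pats, empty_claims())
  pred <- data.frame(patient_id = pats$patient_id,
                     predicted_m = c(rep("POSITIVE", 18), rep("NEGATIVE", 6),
                                     rep("POSITIVE", 4), rep("NEGATIVE", 12)))
  prof <- describe_cells(pred, co)
  expect_equal(unname(prof$n), c(18L, 4L, 6L, 12L))
  g <- function(cell, var, lev) {
    p <- prof$profile
    p$percent[p$cell == cell & p$variable == var & p$level == lev]
  }
  expect_equal(g("TP", "sex", "F"), 100 * 12 / 18)
  expect_equal(g("FN", "sex", "M"), 100)
  expect_equal(g("TP", "death_within_1y", ""), 100 * 12 / 18)
  expect_equal(g("FP", "death_within_1y", ""), 0)
  expect_equal(g("FP", "death_within_5y", ""), 50)

  # every categorical block sums to 100 within rounding
  p <- prof$profile[!startsWith(prof$profile$variable, "death"), ]
  sums <- tapply(p$percent, list(p$cell, p$variable), sum)
  expect_true(all(abs(sums - 100) < 0.2))

  # perfect predictor leaves the discordant cells empty
  perfect <- data.frame(patient_id = pats$patient_id,
                        predicted_m = ifelse(status == "M1", "POSITIVE",
                                             "NEGATIVE"))
  prof2 <- describe_cells(perfect, co)
  expect_equal(unname(prof2$n[c("FP", "FN")]), c(0L, 0L))
  expect_false(any(prof2$profile$cell %in% c("FP", "FN")))
  expect_false(anyNA(prof2$profile$percent))
})

test_that("content validity reports per-cell one-year mortality", {
  # all alive: every percentage is zero
  status <- rep(c("M1", "M0"), 3)
  co <- cohort(make_patients(6, reference_m_status = status),
               empty_claims())
  pred <- data.frame(patient_id = co$patients$patient_id,
                     predicted_m = rep(c("POSITIVE", "NEGATIVE"), 3))
  cv <- content_validity(pred, co)
  expect_equal(cv$death_1y_pct[cv$n > 0], rep(0, sum(cv$n > 0)))

  # single-patient cells give 0 or 100
  pats <- make_patients(2, reference_m_status = c("M1", "M0"),
                        death_date = as.Date(c("2006-07-01", NA)))
  co <- cohort(pats, empty_claims())
  pred <- data.frame(patient_id = pats$patient_id,
                     predicted_m = c("POSITIVE", "POSITIVE"))
  cv <- content_validity(pred, co)
  expect_equal(cv$death_1y_pct[cv$cell == "TP"], 100)
  expect_equal(cv$death_1y_pct[cv$cell == "FP"], 0)

  # under the calibrated simulator, correctly flagged metastatic patients
  # die within a year more often than false positives
  co <- simulate_cohort(simulation_params(n_patients = 1500, seed = 21))
  pred <- classify_cohort(co, algorithm_from_number(12))
  cv <- content_validity(pred, co)
  expect_gt(cv$death_1y_pct[cv$cell == "TP"],
            cv$death_1y_pct[cv$cell == "FP"])
  expect_gt(cv$death_1y_pct[cv$cell == "FN"],
            cv$death_1y_pct[cv$cell == "TN"])
})
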