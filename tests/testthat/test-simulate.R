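test_that("the simulator is deterministic given its seed", {
  a <- simulate_cohort(simulation_params(n_patients = 80, seed = 14))
  b <- simulate_cohort(simulation_params(n_patients = 80, seed = 14))
  expect_equal(a$patients, b$patients)
  expect_equal(a$claims, b$claims)
  c2 <- simulate_cohort(simulation_params(n_patients = 80, seed = 15))
  expect_false(identical(a$claims, c2$claims))
})

test_that("zero prevalence yields no M1 patients and an empty left column", {
  p <- simulation_params(n_patients = 150, seed = 3, prevalence_m1 = 0,
                         prop_unknown = 0)
  co <- simulate_cohort(p)
  expect_false(any(co$patients$reference_m_status == "M1"))
  for (n in c(1, 12, 27)) {
    ct <- confusion(classify_cohort(co, algorithm_from_number(n)), co)
    expect_equal(ct$tp, 0L)
    expect_equal(ct$fn, 0L)
  }
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(simulation_params(prevalence_m1 = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(lambda_hosp_m1 = -1), "non-negative")
  expect_error(simulation_params(p_code_hosp = c(0.8, 0.3, 0.2)),
               "sum to at most 1")
  expect_error(simulation_params(p_code_hosp = c(0.1, 0.1)), "length")
  expect_error(simulation_params(bananas = 1), "unknown simulation")
})

test_that("profiles set the advertised emission regimes", {
  null <- simulation_params(profile = "null")
  expect_true(all(unlist(null[c("p_code_hosp", "p_code_outpt",
                                "q_code_hosp", "q_code_outpt")]) == 0))
  perfect <- simulation_params(profile = "perfect")
  expect_equal(perfect$p_code_hosp, c(1, 0, 0))
  expect_true(all(unlist(perfect[c("q_code_hosp", "q_code_outpt")]) == 0))
  # no coding signal: nothing ever qualifies
  co <- simulate_cohort(simulation_params(n_patients = 100, seed = 5,
                                          profile = "null"))
  pred <- classify_cohort(co, algorithm_from_number(27))
  expect_true(all(pred$predicted_m == "NEGATIVE"))
})

test_that("the oracle reduces to known closed forms in limiting cases", {
  cfg_h1 <- algorithm_config("CONSERVATIVE", "H1", "PRE180_POST180")
  # no coding signal: Se 0, Sp 1
  o <- expected_algorithm_performance(simulation_params(profile = "null"),
                                      cfg_h1)
  expect_equal(o$expected_se, 0)
  expect_equal(o$expected_sp, 1)
  # unit-rate hospitalization stream with certain coding and a window
  # covering the whole claim support: Se = 1 - exp(-1)
  p <- simulation_params(lambda_hosp_m1 = 1, p_code_hosp = c(1, 0, 0),
                         lambda_outpt_m1 = 0, lambda_ed_m1 = 0,
                         date_spread_days = 180)
  o <- expected_algorithm_performance(p, cfg_h1)
  expect_equal(o$expected_se, 1 - exp(-1), tolerance = 1e-12)
})

test_that("expected performance is monotone in rates, emissions and window size", {
  base <- simulation_params()
  cfgs <- enumerate_algorithms()
  se_of <- function(p, n) {
    expected_algorithm_performance(p, cfgs[[n]])$expected_se
  }
  sp_of <- function(p, n) {
    expected_algorithm_performance(p, cfgs[[n]])$expected_sp
  }
  for (n in c(1, 5, 12, 27)) {
    up_lambda <- simulation_params(lambda_hosp_m1 = base$lambda_hosp_m1 * 2)
    expect_gte(se_of(up_lambda, n), se_of(base, n))
    up_p <- simulation_params(p_code_outpt = pmin(base$p_code_outpt * 1.5,
                                                  c(1, 0, 0) + 0.3))
    expect_gte(se_of(up_p, n), se_of(base, n))
    up_q <- simulation_params(q_code_hosp = pmin(base$q_code_hosp * 1.5, 1))
    expect_lte(sp_of(up_q, n), sp_of(base, n))
  }
  # along the window axis at fixed tier and rule
  for (b in c(1, 2, 3)) {
    expect_lte(se_of(base, b), se_of(base, b + 9))   # ±3m vs ±6m
    expect_lte(se_of(base, b), se_of(base, b + 18))  # ±3m vs no-limit
    expect_gte(sp_of(base, b), sp_of(base, b + 9))
    expect_gte(sp_of(base, b), sp_of(base, b + 18))
  }
})

test_that("empirical algorithm performance tracks the oracle at moderate n", {
  p <- simulation_params(n_patients = 8000, seed = 23)
  co <- simulate_cohort(p)
  ref <- co$patients$reference_m_status
  n1 <- sum(ref == "M1")
  n0 <- sum(ref != "M1")
  for (n in c(1, 12, 18, 27)) {
    cfg <- algorithm_from_number(n)
    m <- diagnostic_metrics(confusion(classify_cohort(co, cfg), co))
    o <- expected_algorithm_performance(p, cfg)
    se_tol <- 4 * sqrt(o$expected_se * (1 - o$expected_se) / n1)
    sp_tol <- 4 * sqrt(o$expected_sp * (1 - o$expected_sp) / n0)
    expect_equal(m[["sensitivity"]], o$expected_se, tolerance = se_tol)
    expect_equal(m[["specificity"]], o$expected_sp, tolerance = sp_tol)
  }
})

test_that("the default profile reproduces its cohort margins", {
  # pool several simulated cohorts for a stable estimate of the margins
  ref <- character()
  dead1 <- logical()
  for (seed in 31:35) {
    co <- simulate_cohort(simulation_params(n_patients = 2366, seed = seed))
    ref <- c(ref, co$patients$reference_m_status)
    dead1 <- c(dead1, !is.na(co$patients$death_date) &
                 co$patients$death_date <= co$patients$diagnosis_date + 365)
  }
  n <- length(ref)
  m1 <- ref == "M1"
  expect_lt(abs(mean(m1) - 0.543), 3 * sqrt(0.543 * 0.457 / n))
  expect_lt(abs(mean(dead1[m1]) - 0.719),
            3 * sqrt(0.719 * 0.281 / sum(m1)))
  expect_lt(abs(mean(dead1[!m1]) - 0.325),
            3 * sqrt(0.325 * 0.675 / sum(!m1)))
  # unknown reference status share near its target rate
  expect_lt(abs(mean(ref == "UNKNOWN") - 0.043),
            3 * sqrt(0.043 * 0.957 / n))
})

test_that("calibration recovers known emission parameters from oracle targets", {
  truth <- simulation_params(p_code_hosp = c(0.30, 0.10, 0.12),
                             p_code_outpt = c(0.08, 0.05, 0.10),
                             q_code_hosp = c(0.10, 0.06, 0.08),
                             q_code_outpt = c(0.02, 0.015, 0.05))
  targets <- do.call(rbind, lapply(1:27, function(n) {
    o <- expected_algorithm_performance(truth, algorithm_from_number(n))
    data.frame(algorithm_number = n, se = o$expected_se,
               sp = o$expected_sp)
  }))
  start <- simulation_params(p_code_hosp = c(0.5, 0.05, 0.05),
                             p_code_outpt = c(0.15, 0.05, 0.2),
                             q_code_hosp = c(0.2, 0.1, 0.05),
                             q_code_outpt = c(0.05, 0.01, 0.1))
  fit <- calibrate_params(targets, params = start)
  for (f in c("p_code_hosp", "p_code_outpt", "q_code_hosp",
              "q_code_outpt")) {
    rel <- abs(fit$params[[f]] - truth[[f]]) / truth[[f]]
    expect_true(all(rel <= 0.05), info = f)
  }
  expect_true(all(fit$rmse < 1e-4, na.rm = TRUE))
})

test_that("a single-algorithm target is flagged as underdetermined", {
  expect_warning(
    calibrate_params(data.frame(algorithm_number = 12, se = 0.686,
                                sp = 0.791)),
    "underdetermined")
})
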