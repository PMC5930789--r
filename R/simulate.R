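# Synthetic linked-claims cohort generator.
#
# Generative model (one patient):
#   reference M status ~ Bernoulli(prevalence_m1); a fraction prop_unknown of
#   the cohort, drawn from the non-M1 side, gets UNKNOWN reference status
#   (their claims behave like M0).  AJCC stage is IV for M1, sampled over
#   I-III/unknown otherwise.  Death time ~ Exponential with rate calibrated
#   so P(death <= 365 d) equals the class's one-year mortality.  Per source
#   (hospitalization / outpatient / ED) the claim count is Poisson with a
#   class-specific mean; claim dates are i.i.d. uniform over the integer
#   offsets -date_spread_days .. +date_spread_days around diagnosis.  Each
#   claim carries one diagnosis code drawn from a four-way category mixture:
#   secondary malignancy, unspecified-site malignancy, other non-digestive
#   malignancy, or benign filler, with class- and source-specific incremental
#   probabilities (the emission triples); the cumulative sums give the
#   probability that a claim qualifies under each code-list tier.  Extra
#   background claims carry benign codes only.
#
# Because dates are uniform and codes independent, every algorithm's
# expected sensitivity/specificity has a closed form (see
# expected_algorithm_performance), which is what makes the generator usable
# as an analytic oracle.

# code pools per ICD version x emission category; the benign pool is
# disjoint from every default tier
SIM_CODE_POOLS <- list(
  `9` = list(secondary = c("196", "1960", "197", "1970", "1977", "198", "1983"),
             unspecified = c("199", "1991", "195"),
             other_malig = c("174", "185", "162", "188", "1629"),
             benign = c("401", "250", "535", "789", "4019")),
  `10` = list(secondary = c("C77", "C779", "C780", "C787", "C792", "C795"),
              unspecified = c("C809", "C80", "C768"),
              other_malig = c("C509", "C61", "C349", "C679", "C719"),
              benign = c("I10", "E119", "K219", "R104", "J189"))
)

# class-conditional covariate distributions used by the generator; the age,
# sex, tumour-location and Charlson columns follow the validation cohort's
# published margins (normalized to sum to one), T/N stage profiles are
# stylized
SIM_COVARIATES <- list(
  age = list(M1 = c(10.9, 6.9, 8.9, 10.4, 13.3, 49.6),
             M0 = c(6.8, 5.9, 8.6, 10.5, 11.8, 56.2)),
  female = c(M1 = 0.35, M0 = 0.355),
  tumour = list(M1 = c(32.9, 9.8, 27.3, 15.6, 9.8, 4.7),
                M0 = c(43.8, 5.1, 23.5, 17.1, 6.9, 3.6)),
  charlson = list(M1 = c(56.9, 28.6, 12.5, 6.9),
                  M0 = c(47.8, 30.6, 4.7, 11)),
  t_stage = list(M1 = c(4, 4, 20, 20, 8, 44),
                 M0 = c(18, 12, 30, 20, 5, 15)),
  n_status = list(M1 = c(18, 8, 10, 7, 4, 53),
                  M0 = c(38, 14, 13, 11, 4, 20)),
  ajcc_m0 = c(12, 10, 9, 8, 9, 12, 11, 29)  # over non-IV levels + unknown
)

# emission triples of the published profile, obtained by least-squares
# inversion of the analytic oracle against the reference performance table
# (see calibrate_params); frozen here so the default profile is stable
PUBLISHED_EMISSION <- list(
  p_code_hosp  = c(0.99990, 0.00001, 0.00001),
  p_code_outpt = c(0.17990, 0.06402, 0.37463),
  q_code_hosp  = c(0.32872, 0.09442, 0.04919),
  q_code_outpt = c(0.04861, 0.00422, 0.24222)
)

#' Parameters of the synthetic claims simulator
#'
#' Assembles and validates the full parameter set of the generative model.
#' The defaults are the `published` profile: prevalence and one-year
#' mortality equal to the validation cohort's published margins (54.3% M1;
#' 71.9% vs 32.5% one-year mortality) and code-emission probabilities
#' calibrated so the 27 algorithms' expected operating points resemble the
#' published ones.  Profiles:
#'
#' * `published` — the calibrated default.
#' * `null` — no coding signal (`p = q = 0`): every algorithm has expected
#'   sensitivity 0 and specificity 1.
#' * `perfect` — every M1 claim carries a secondary-malignancy code and no
#'   M0 claim ever does (`p = (1,0,0)`, `q = 0`).
#'
#' Emission fields are length-3 incremental probability vectors over the
#' categories (secondary, unspecified-site, other non-digestive malignancy);
#' their cumulative sums are the per-claim probabilities of qualifying under
#' the conservative, less conservative and inclusive tier respectively.
#'
#' @param n_patients Cohort size (default 2366).
#' @param profile `"published"`, `"null"` or `"perfect"`.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param ... Named overrides of any parameter (e.g. `prevalence_m1`,
#'   `lambda_hosp_m1`, `p_code_hosp`, `date_spread_days`, ...).
#' @return Object of class `simulation_params` (a validated named list).
#' @export
simulation_params <- function(n_patients = 2366,
                              profile = c("published", "null", "perfect"),
                              seed = 1L, ...) {
  profile <- match.arg(profile)
  p <- list(
    n_patients = as.integer(n_patients), profile = profile,
    seed = as.integer(seed),
    prevalence_m1 = 0.543, prop_unknown = 0.043,
    mortality_1y_m1 = 0.719, mortality_1y_m0 = 0.325,
    lambda_hosp_m1 = 2.0, lambda_hosp_m0 = 1.5,
    lambda_outpt_m1 = 6.0, lambda_outpt_m0 = 5.0,
    lambda_ed_m1 = 0, lambda_ed_m0 = 0,
    p_code_hosp = PUBLISHED_EMISSION$p_code_hosp,
    p_code_outpt = PUBLISHED_EMISSION$p_code_outpt,
    q_code_hosp = PUBLISHED_EMISSION$q_code_hosp,
    q_code_outpt = PUBLISHED_EMISSION$q_code_outpt,
    background_hosp = 0.5, background_outpt = 3.0, background_ed = 0.3,
    date_spread_days = 365L,
    p_resect_m1 = 0.25, p_resect_m0 = 0.60)
  if (profile == "null") {
    p[c("p_code_hosp", "p_code_outpt", "q_code_hosp", "q_code_outpt")] <-
      list(rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  } else if (profile == "perfect") {
    p$p_code_hosp <- c(1, 0, 0)
    p$p_code_outpt <- c(1, 0, 0)
    p$q_code_hosp <- rep(0, 3)
    p$q_code_outpt <- rep(0, 3)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) {
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  if (p$n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  check_prob(c(p$prevalence_m1, p$prop_unknown, p$mortality_1y_m1,
               p$mortality_1y_m0, p$p_resect_m1, p$p_resect_m0),
             "prevalence/mortality/resection parameters")
  check_rate(c(p$lambda_hosp_m1, p$lambda_hosp_m0, p$lambda_outpt_m1,
               p$lambda_outpt_m0, p$lambda_ed_m1, p$lambda_ed_m0,
               p$background_hosp, p$background_outpt, p$background_ed),
             "claim rates")
  for (f in c("p_code_hosp", "p_code_outpt", "q_code_hosp", "q_code_outpt")) {
    v <- p[[f]]
    if (length(v) == 1) v <- c(v, 0, 0)  # scalar = conservative-only
    if (length(v) != 3) stop(f, " must have length 1 or 3", call. = FALSE)
    check_prob(v, f)
    if (sum(v) > 1) stop(f, " components must sum to at most 1",
                         call. = FALSE)
    p[[f]] <- v
  }
  if (p$date_spread_days < 1) stop("date_spread_days must be >= 1",
                                   call. = FALSE)
  p$date_spread_days <- as.integer(p$date_spread_days)
  structure(p, class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf("<simulation_params> profile=%s n=%d seed=%d prevalence=%.3f\n",
              x$profile, x$n_patients, x$seed, x$prevalence_m1))
  cat(sprintf("  tier-cumulative qualifying prob, hosp M1: %s | M0: %s\n",
              paste(sprintf("%.3f", cumsum(x$p_code_hosp)), collapse = "/"),
              paste(sprintf("%.3f", cumsum(x$q_code_hosp)), collapse = "/")))
  invisible(x)
}

sample_level <- function(n, levels, weights) {
  w <- weights / sum(weights)
  levels[sample.int(length(levels), n, replace = TRUE, prob = w)]
}

draw_codes <- function(cat_idx, icd_version) {
  pools <- SIM_CODE_POOLS[[as.character(icd_version)]]
  nms <- c("secondary", "unspecified", "other_malig", "benign")
  out <- character(length(cat_idx))
  for (k in seq_along(nms)) {
    sel <- cat_idx == k
    if (any(sel)) {
      out[sel] <- sample(pools[[nms[k]]], sum(sel), replace = TRUE)
    }
  }
  out
}

# one claim stream: Poisson counts per patient, uniform dates, category draw
sim_stream <- function(pid, diag, lambda, source, icd_version, emission,
                       spread, extra_benign = FALSE) {
  cnt <- stats::rpois(length(pid), lambda)
  m <- sum(cnt)
  if (m == 0) return(NULL)
  idx <- rep.int(seq_along(pid), cnt)
  off <- sample.int(2L * spread + 1L, m, replace = TRUE) - spread - 1L
  cum <- cumsum(emission)
  cat_idx <- findInterval(stats::runif(m), cum) + 1L
  codes <- draw_codes(cat_idx, icd_version)
  if (extra_benign) {
    # hospital abstracts usually carry several diagnoses; pad with benign
    # codes (never tier-qualifying) to exercise any-position matching
    nx <- sample(0:2, m, replace = TRUE)
    pool <- SIM_CODE_POOLS[[as.character(icd_version)]]$benign
    extras <- vapply(nx, function(k) {
      if (k == 0) "" else paste(sample(pool, k, replace = TRUE),
                                collapse = ";")
    }, character(1))
    codes <- ifelse(nzchar(extras), paste(codes, extras, sep = ";"), codes)
  }
  data.frame(patient_id = pid[idx], source = source,
             service_date = diag[idx] + off,
             icd_version = icd_version, codes = codes,
             stringsAsFactors = FALSE)
}

#' Simulate a linked cohort + claims data set
#'
#' Draws a synthetic cohort from the generative model described in
#' [simulation_params()].  Hospitalization and ED claims carry ICD-10 codes
#' (discharge-abstract dialect), outpatient claims ICD-9 codes (3-digit
#' physician-billing dialect).  Deterministic given `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A [cohort()] object whose provenance records the simulator seed
#'   and parameters.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_params(n_patients = 200, seed = 7))
#' co
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_patients
  pid <- sprintf("P%05d", seq_len(n))
  is_m1 <- stats::runif(n) < params$prevalence_m1
  ref <- ifelse(is_m1, "M1", "M0")
  if (params$prop_unknown > 0 && any(!is_m1)) {
    p_u <- min(1, params$prop_unknown / max(1e-12, 1 - params$prevalence_m1))
    unk <- !is_m1 & stats::runif(n) < p_u
    ref[unk] <- "UNKNOWN"
  }
  diag <- as.Date("2005-04-01") + sample.int(1095L, n, replace = TRUE) - 1L

  cls <- ifelse(is_m1, "M1", "M0")  # UNKNOWN behaves like M0 throughout
  pick <- function(tab) ifelse(cls == "M1", tab[["M1"]], tab[["M0"]])
  draw2 <- function(levels, tab) {
    out <- character(n)
    for (g in c("M1", "M0")) {
      sel <- cls == g
      if (any(sel)) out[sel] <- sample_level(sum(sel), levels, tab[[g]])
    }
    out
  }
  age <- draw2(AGE_LEVELS, SIM_COVARIATES$age)
  sex <- ifelse(stats::runif(n) < pick(as.list(SIM_COVARIATES$female)),
                "F", "M")
  tumour <- draw2(TUMOUR_LEVELS, SIM_COVARIATES$tumour)
  charlson <- draw2(CHARLSON_LEVELS, SIM_COVARIATES$charlson)
  tstage <- draw2(T_LEVELS, SIM_COVARIATES$t_stage)
  nstatus <- draw2(N_LEVELS, SIM_COVARIATES$n_status)
  ajcc <- rep("unknown", n)
  ajcc[is_m1] <- "IV"
  m0 <- ref == "M0"
  if (any(m0)) {
    ajcc[m0] <- sample_level(sum(m0), setdiff(AJCC_LEVELS, "IV"),
                             SIM_COVARIATES$ajcc_m0)
  }
  mort <- ifelse(is_m1, params$mortality_1y_m1, params$mortality_1y_m0)
  # exponential survival with P(T <= 365) = class 1-year mortality
  rate <- -log(pmax(1e-12, 1 - mort)) / 365
  death_day <- ceiling(stats::rexp(n, rate))
  death <- diag + death_day
  death[death_day > 3652] <- NA  # administratively alive past ~10 years
  resected <- stats::runif(n) <
    ifelse(is_m1, params$p_resect_m1, params$p_resect_m0)

  patients <- data.frame(
    patient_id = pid, diagnosis_date = diag, reference_m_status = ref,
    death_date = death, age_group = age, sex = sex,
    tumour_location = tumour, charlson_category = charlson,
    t_stage = tstage, n_status = nstatus, ajcc_stage = ajcc,
    resected = resected, stringsAsFactors = FALSE)

  S <- params$date_spread_days
  zero3 <- rep(0, 3)
  # emission differs by class, so each stream is drawn per class
  streams <- list()
  for (g in c(TRUE, FALSE)) {
    sel <- is_m1 == g
    if (!any(sel)) next
    ph <- if (g) params$p_code_hosp else params$q_code_hosp
    po <- if (g) params$p_code_outpt else params$q_code_outpt
    lh <- if (g) params$lambda_hosp_m1 else params$lambda_hosp_m0
    lo <- if (g) params$lambda_outpt_m1 else params$lambda_outpt_m0
    le <- if (g) params$lambda_ed_m1 else params$lambda_ed_m0
    streams <- c(streams, list(
      sim_stream(pid[sel], diag[sel], lh, "HOSPITALIZATION", 10L, ph, S,
                 extra_benign = TRUE),
      sim_stream(pid[sel], diag[sel], lo, "OUTPATIENT", 9L, po, S),
      if (le > 0) sim_stream(pid[sel], diag[sel], le, "ED", 10L, po, S)))
  }
  # background claims: benign codes only, both classes alike
  streams <- c(streams, list(
    sim_stream(pid, diag, params$background_hosp, "HOSPITALIZATION", 10L,
               zero3, S, extra_benign = TRUE),
    sim_stream(pid, diag, params$background_outpt, "OUTPATIENT", 9L,
               zero3, S),
    if (params$background_ed > 0)
      sim_stream(pid, diag, params$background_ed, "ED", 10L, zero3, S)))
  streams <- Filter(Negate(is.null), streams)
  claims <- if (length(streams)) do.call(rbind, streams) else
    data.frame(patient_id = character(), source = character(),
               service_date = as.Date(character()),
               icd_version = integer(), codes = character(),
               stringsAsFactors = FALSE)

  cohort(patients, claims,
         provenance = list(simulator = "m1claims::simulate_cohort",
                           seed = params$seed, profile = params$profile,
                           params = unclass(params)))
}

# number of integer day-offsets of the claim support inside a window
window_support_days <- function(window, spread) {
  win <- switch(window,
                PRE90_POST90 = c(-90, 90),
                PRE180_POST180 = c(-180, 180),
                PRE90_NOLIMIT = c(-90, Inf))
  lo <- max(win[1], -spread)
  hi <- min(win[2], spread)
  max(0, hi - lo + 1)
}

#' Closed-form expected performance of an algorithm under the simulator
#'
#' Exact expected sensitivity and specificity of an [algorithm_config()]
#' under the generative model of [simulation_params()].  With claim dates
#' i.i.d. uniform over `D = 2*date_spread_days + 1` integer offsets and
#' independent per-claim coding, the qualifying hospitalization count inside
#' a window covering `k` of those offsets is Poisson with mean
#' `lambda_h * e * k / D` (`e` = tier-cumulative emission probability), and
#' the number of *distinct* qualifying outpatient service dates is
#' Binomial(`k`, `1 - exp(-lambda_o * e / D)`) by day-level Poisson
#' splitting.  The source rules then give, per class,
#' `P(negative) = P(hosp = 0) * P(outpatient arm below threshold)`;
#' sensitivity uses the M1 emission parameters, specificity the M0 ones.
#'
#' @param params A [simulation_params()].
#' @param config An [algorithm_config()].
#' @return Object of class `oracle_result`: list with `config`,
#'   `expected_se`, `expected_sp`.
#' @export
#' @examples
#' pr <- simulation_params(lambda_hosp_m1 = 1, p_code_hosp = c(1, 0, 0))
#' cfg <- algorithm_config("CONSERVATIVE", "H1", "PRE180_POST180")
#' expected_algorithm_performance(pr, cfg)$expected_se  # 1 - exp(-1)
expected_algorithm_performance <- function(params, config) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(config, "algorithm_config"))
  S <- params$date_spread_days
  D <- 2 * S + 1
  k <- window_support_days(config$window, S)
  ti <- match(config$tier, TIER_LEVELS)
  ed_on <- config$ed_policy == "ED_AS_OUTPATIENT"
  neg_prob <- function(l_h, l_o, l_ed, em_h, em_o) {
    e_h <- cumsum(em_h)[ti]
    e_o <- cumsum(em_o)[ti]
    mu_h <- l_h * e_h * k / D
    r <- (l_o * e_o + (if (ed_on) l_ed else 0) * e_o) / D
    th <- 1 - exp(-r)
    p0 <- (1 - th)^k
    p1 <- k * th * (1 - th)^(max(0, k - 1))
    switch(config$source_rule,
           H1 = exp(-mu_h),
           H1_OR_O2 = exp(-mu_h) * (p0 + p1),
           H1_OR_O1 = exp(-mu_h) * p0)
  }
  se <- 1 - neg_prob(params$lambda_hosp_m1, params$lambda_outpt_m1,
                     params$lambda_ed_m1, params$p_code_hosp,
                     params$p_code_outpt)
  sp <- neg_prob(params$lambda_hosp_m0, params$lambda_outpt_m0,
                 params$lambda_ed_m0, params$q_code_hosp,
                 params$q_code_outpt)
  structure(list(config = config, expected_se = se, expected_sp = sp),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result>%s expected Se=%.4f Sp=%.4f\n",
              if (is.null(x$config$algorithm_number)) "" else
                sprintf(" #%d", x$config$algorithm_number),
              x$expected_se, x$expected_sp))
  invisible(x)
}

# bijection between an unconstrained 3-vector and a monotone cumulative
# emission profile in (0, 1)
a_to_emission <- function(a) {
  c1 <- stats::plogis(a[1])
  c2 <- c1 + (1 - c1) * stats::plogis(a[2])
  c3 <- c2 + (1 - c2) * stats::plogis(a[3])
  c(c1, c2 - c1, c3 - c2)
}

emission_to_a <- function(p) {
  cum <- pmin(pmax(cumsum(p), 1e-6), 1 - 1e-6)
  a1 <- stats::qlogis(cum[1])
  a2 <- stats::qlogis(pmin(pmax((cum[2] - cum[1]) / (1 - cum[1]), 1e-6),
                           1 - 1e-6))
  a3 <- stats::qlogis(pmin(pmax((cum[3] - cum[2]) / (1 - cum[2]), 1e-6),
                           1 - 1e-6))
  c(a1, a2, a3)
}

#' Calibrate emission probabilities to target operating points
#'
#' Least-squares inversion of the analytic oracle: finds the code-emission
#' triples (hospitalization and outpatient, for the M1 and M0 classes) whose
#' expected sensitivity/specificity best match the supplied per-algorithm
#' targets, holding the claim-rate parameters of `params` fixed.  The M1
#' parameters are fitted to the sensitivity targets and the M0 parameters to
#' the specificity targets (the two classes are independent in the model).
#' With fewer than two target algorithms the fit is underdetermined and a
#' warning is issued; a fit whose residuals remain large (targets not
#' representable within the model, e.g. an ordering the uniform-date model
#' cannot produce) also warns and reports the residuals.
#'
#' @param targets Data frame with columns `algorithm_number` and at least
#'   one of `se`, `sp` (proportions, or percentages if any value exceeds 1).
#'   Defaults to the shipped reference performance table.
#' @param params Starting [simulation_params()]; claim rates are kept.
#' @return Object of class `calibration_fit`: list with `params` (fitted),
#'   `residuals` (per-target data frame with fitted values), and the root
#'   mean squared residual per side.
#' @export
calibrate_params <- function(targets = reference_performance(),
                             params = simulation_params()) {
  targets <- as.data.frame(targets)
  if (!"algorithm_number" %in% names(targets)) {
    stop("targets must have a column algorithm_number", call. = FALSE)
  }
  if (nrow(targets) < 2) {
    warning("fewer than two target algorithms: emission parameters are underdetermined",
            call. = FALSE)
  }
  for (m in c("se", "sp")) {
    if (m %in% names(targets) && any(targets[[m]] > 1, na.rm = TRUE)) {
      targets[[m]] <- targets[[m]] / 100
    }
  }
  configs <- lapply(targets$algorithm_number, algorithm_from_number)

  fit_side <- function(metric, fields) {
    if (!metric %in% names(targets)) return(NULL)
    tv <- targets[[metric]]
    ok <- !is.na(tv)
    obj <- function(a) {
      pp <- params
      pp[[fields[1]]] <- a_to_emission(a[1:3])
      pp[[fields[2]]] <- a_to_emission(a[4:6])
      fit <- vapply(configs[ok], function(cfg) {
        o <- expected_algorithm_performance(pp, cfg)
        if (metric == "se") o$expected_se else o$expected_sp
      }, numeric(1))
      sum((fit - tv[ok])^2)
    }
    a0 <- c(emission_to_a(params[[fields[1]]]),
            emission_to_a(params[[fields[2]]]))
    opt <- stats::optim(a0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    list(e1 = a_to_emission(opt$par[1:3]), e2 = a_to_emission(opt$par[4:6]),
         value = opt$value, n = sum(ok))
  }

  fit_se <- fit_side("se", c("p_code_hosp", "p_code_outpt"))
  fit_sp <- fit_side("sp", c("q_code_hosp", "q_code_outpt"))
  out <- params
  if (!is.null(fit_se)) {
    out$p_code_hosp <- fit_se$e1
    out$p_code_outpt <- fit_se$e2
  }
  if (!is.null(fit_sp)) {
    out$q_code_hosp <- fit_sp$e1
    out$q_code_outpt <- fit_sp$e2
  }
  res <- data.frame(algorithm_number = targets$algorithm_number)
  fitted <- lapply(configs, expected_algorithm_performance, params = out)
  if ("se" %in% names(targets)) {
    res$se_target <- targets$se
    res$se_fit <- vapply(fitted, `[[`, numeric(1), "expected_se")
  }
  if ("sp" %in% names(targets)) {
    res$sp_target <- targets$sp
    res$sp_fit <- vapply(fitted, `[[`, numeric(1), "expected_sp")
  }
  rmse <- c(se = if (is.null(fit_se)) NA_real_ else
    sqrt(fit_se$value / fit_se$n),
    sp = if (is.null(fit_sp)) NA_real_ else sqrt(fit_sp$value / fit_sp$n))
  if (any(rmse > 0.05, na.rm = TRUE)) {
    warning(sprintf(
      "targets not fully representable within the generative model (RMSE se=%.3f, sp=%.3f); see residuals",
      rmse[["se"]], rmse[["sp"]]), call. = FALSE)
  }
  structure(list(params = out, residuals = res, rmse = rmse),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %d target algorithm(s); RMSE se=%.4f sp=%.4f\n",
              nrow(x$residuals), x$rmse[["se"]], x$rmse[["sp"]]))
  invisible(x)
}
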