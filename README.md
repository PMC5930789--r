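# m1claims

Case-finding algorithms for metastatic (M1) gastric cancer in
administrative health claims, with a validated evaluation pipeline.

## The problem

Population-based cancer registries often lack TNM stage, which makes it
hard to assemble metastatic cohorts for health-services research. When a
registry cohort can be linked to routine administrative data —
hospital discharge abstracts, emergency-department records and physician
billing — metastatic disease can instead be *inferred* from the diagnosis
codes on those records. `m1claims` implements a family of 27 deterministic
case-finding rules of the form

> flag the patient as M1 if their claims carry a qualifying metastasis
> diagnosis code, from a given **code-list tier**, on a given
> **record-source pattern**, inside a given **peri-diagnosis window**,

together with the machinery to validate any such rule against a
chart-review reference standard. It is aimed at epidemiologists and
health-services researchers who work with linked claims data and need
transparent, re-usable phenotyping rules with honest operating
characteristics.

The three axes are:

* **Code tier** — `CONSERVATIVE` (secondary malignant neoplasm codes only:
  ICD-9 196–198, ICD-10 C77–C79), `LESS_CONSERVATIVE` (adds
  unspecified/ill-defined-site malignancy: ICD-9 195, 199; ICD-10 C76,
  C80), `INCLUSIVE` (any malignancy except digestive organs, so a primary
  gastric code never counts as metastasis evidence). Matching is by code
  prefix, so 3-digit billing codes and 4–5 character discharge codes share
  one list.
* **Source rule** — `H1` (1+ hospitalization), `H1_OR_O2`
  (1+ hospitalization or 2+ outpatient visit dates), `H1_OR_O1`
  (1+ hospitalization or 1+ outpatient visit date).
* **Window** — ±3 months, ±6 months, or −3 months with no post-diagnosis
  limit, all in exact days (90/180) around the registry diagnosis date.

Validation against per-patient reference M status uses the standard 2×2
machinery: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV, NPV and
accuracy `(TP+TN)/(TP+TN+FP+FN)`, each with percentile-bootstrap 95%
confidence intervals (patients resampled with replacement), plus
discordance profiling of the TP/FP/FN/TN cells and a content-validity check
that correctly-flagged metastatic patients show the expected excess
one-year mortality.

Because real linked claims cannot be shared, the package ships a synthetic
cohort simulator (Poisson claim streams, independent per-claim code
emission, exponential survival) whose every algorithm has a closed-form
expected sensitivity and specificity — an analytic oracle used to test the
whole pipeline end to end, and a calibration routine that inverts the
oracle to match published operating points.

## Worked example

```r
library(m1claims)

# a synthetic linked cohort under the calibrated default profile
co <- simulate_cohort(simulation_params(n_patients = 2366, seed = 1))
co
#> <claims_cohort> 2366 patients, 26391 claims
#>   reference status: M1 1333 (56.3%), M0 932, UNKNOWN 101
#>   claims by source: hospitalization 5427, ED 735, outpatient 20229

# algorithm 12: conservative codes, 1+ hospitalization or 1+ outpatient
# date, +/- 6 months around diagnosis
cfg  <- algorithm_from_number(12)
pred <- classify_cohort(co, cfg)
ct   <- confusion(pred, co)
ct
#> <confusion_table> TP=1066 FP=328 FN=267 TN=705 (excluded unknown: 0, policy AS_M0)
round(100 * diagnostic_metrics(ct), 1)
#> sensitivity specificity         ppv         npv    accuracy
#>        80.0        68.2        76.5        72.5        74.9

bootstrap_ci(co, cfg, "sensitivity", n_bootstrap = 1000, seed = 1001)
#> <metric_estimate> sensitivity = 0.7997, 95% CI [0.7784, 0.8206] (B=1000, 0 undefined, seed=1001)

# what the generative model says this algorithm should achieve
expected_algorithm_performance(simulation_params(seed = 1), cfg)
#> <oracle_result> #12 expected Se=0.7814 Sp=0.6952
```

Reading: of the 1333 truly metastatic patients this rule recovers 80.0%,
while flagging 328 of the 1033 non-metastatic ones (specificity 68.2%);
76.5% of flagged patients are truly M1. The analytic oracle (Se 78.1%,
Sp 69.5%) agrees with the empirical run to within sampling noise — the
package's core correctness property.

A full 27-row report (one line per algorithm, every metric with its CI) is
one call, or one shell command via the bundled CLI:

```r
report <- evaluate_all(co, n_bootstrap = 1000, seed = 7)
render_report(report, "markdown", "table2.md")
```

```sh
Rscript inst/cli/m1claims simulate --n 2366 --seed 42 \
    --out-patients P.csv --out-claims C.csv
Rscript inst/cli/m1claims evaluate --patients P.csv --claims C.csv \
    --all-algorithms --bootstrap 5000 --seed 17 --out table2.csv
```

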