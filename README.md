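# colipk

Population pharmacokinetics and dose optimization of intravenous colistin
sulfate in critically ill patients.

Colistin sulfate — the active sulfate salt of colistin (polymyxin E), dosed
in million units (MU; 10,000 IU = 0.44 mg) — shows large exposure
variability in the critically ill, and its efficacy tracks the unbound
exposure-to-MIC ratio (fAUC/MIC). `colipk` is a complete, tested pipeline
for the population-PK analysis such a drug requires, aimed at
pharmacometricians and clinical-pharmacology researchers:

* **Structural model.** A linear two-compartment IV-infusion model evaluated
  in closed form (macro-exponential constants, analytic interval AUCs), with
  the covariate equations

  ```
  V   = tvV  · exp(ηV)
  V2  = tvV2 · (ALT/ALTref)^θALT
  CL  = tvCL · (CrCL/CrCLref)^θCrCL · exp(ηCL)
  CL2 = tvCL2
  ```

  log-normal inter-individual variability on V and CL, and a proportional
  residual-error model. Default parameters are the published final
  estimates (tvV 16.1 L, tvV2 50.5 L, tvCL 1.50 L/h, tvCL2 1.71 L/h,
  exponents 0.635/0.353, ω²V 0.0267, ω²CL 0.197, σ 0.228).
* **Estimation.** A Laplace-approximation (FOCE-class) marginal-likelihood
  engine in C++ (Rcpp/RcppArmadillo): `fit_ppk()`, model comparison by
  AIC/BIC, stepwise covariate modeling (`scm()`, ΔOFV 3.84 forward / 6.63
  backward), subject-level bootstrap (`bootstrap_ppk()`) and a
  prediction-corrected visual predictive check (`pcvpc()`).
* **Renal excretion.** Noncompartmental urinary analysis: amount excreted,
  recovery % of dose, CL_R = Ae/AUC (trapezoid on observed plasma samples),
  renal fraction of total clearance (`renal_summary()`, `renal_report()`).
* **Dose optimization.** Monte Carlo simulation over 12 regimens × CrCL
  {10, 50, 80, 120} ml/min × MIC {0.5, 1, 2} mg/L: PTA of fAUC/MIC ≥ 20
  (f = 0.49) and Css,avg target attainment (>80% for ≥2 mg/L, <30% for
  ≥4 mg/L), with decision rules (`run_simulation()`, `recommend()`).
* **Exposure–outcome.** ROC curves and Mann–Whitney-equivalent AUC_ROC for
  AUCss,0–24/MIC and steady-state concentrations vs binary clinical outcome.
* **Synthetic studies.** `generate_study()` emulates a 20-patient
  critically-ill TDM cohort (CrCL 6.5–193.8 ml/min, ALT 7–495 U/L, ~98
  plasma samples split trough/peak/random 38:27:33, urine collection in 6
  patients) with the hidden truth returned for validation.

Event datasets use a NONMEM-compatible CSV dialect (ID, TIME, AMT, RATE,
EVID, DV, MDV + covariate columns); see `read_dataset()` / `write_dataset()`.

## Worked example

```r
library(colipk)

# a virtual study shaped like the clinical cohort, truth returned separately
gen <- generate_study(study_design(n_patients = 20, seed = 7))

# fit the final covariate model (CrCL on CL, ALT on V2)
fit <- fit_ppk(final_model_spec(), gen$study)
print(fit)
#> Population PK fit (2-compartment, proportional error)
#>   -2LL 79.75 | AIC 97.75 | BIC 120.45 | 20 subjects, 92 obs
#>            Estimate   CV%
#> tvV        1.46e+01  7.02
#> tvV2       9.51e+01 24.80
#> tvCL       1.08e+00 14.20
#> tvCL2      1.50e+00 17.60
#> dCLdCRCL   2.07e-01 46.90
#> dV2dALT    5.79e-01 24.50
#> omega2_V   4.75e-07 30.80
#> omega2_CL  1.59e-01 51.70
#> sigma_prop 1.96e-01  8.42
#>   shrinkage (%): eta_V 99.8, eta_CL 5.25

# typical subject at the reference covariates and a label regimen
ind <- individual_params(fit_to_pop_params(fit),
                         covariates(crcl = 57.5, alt = 37,
                                    weight = 55, age = 60))
exposure_metrics(ind, regimen(0.75, 12), eval_day = 3)$css_avg
#> [1] 1.523531

# Monte Carlo attainment across the regimen grid
grid <- run_simulation(generate_true_params(),
                       sim_scenario(n_replicates = 1000, seed = 1))
head(recommend(grid, mic = 2), 3)
#>      regimen crcl pta prob_over_2 prob_over_4 css_avg_median pta_pass
#> 1 0.5MU q12h   10   0         1.4           0      1.3845389    FALSE
#> 2 0.5MU q12h  120   0         0.0           0      0.7969261    FALSE
#> 3 0.5MU q12h   50   0         0.0           0      0.9944674    FALSE
#>   efficacy_pass toxicity_pass verdict
#> 1         FALSE          TRUE   FALSE
#> 2         FALSE          TRUE   FALSE
#> 3         FALSE          TRUE   FALSE
```

The printed fit shows each parameter's estimate with its CV%; on a single
20-patient sparse cohort the variability terms are weakly identified
(ω²V collapses toward zero with ~100% eta-shrinkage) — exactly the
behaviour the bootstrap quantifies on the real cohort, and the reason the
parameter-recovery protocol below uses an enriched design. The `css_avg`
value (mg/L) is this cohort-fitted typical patient's day-3 interval average
for 0.75 MU q12h; `recommend()` marks each regimen × CrCL cell pass/fail on
the PTA, efficacy and toxicity rules (at MIC 2 mg/L, low-dose cells fail
the PTA rule, matching the expectation that label doses are insufficient at
the susceptibility breakpoint).

A command-line wrapper covering the workflow stages (`generate`, `fit`,
`scm`, `bootstrap`, `vpc`, `renal`, `pta`, `roc`) is installed at
`inst/cli/colipk`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates 10 virtual studies of 200 patients from the published final
estimates at an enriched sampling design (0.75 MU q12h, 2-h infusions,
8 samples across the 60–72 h interval), refits the covariate model from
scratch with the package's estimation engine, and writes the median
estimate of each structural parameter (tvCL, the CrCL exponent, tvV2, the
ALT exponent, tvV, tvCL2, ω²CL and σ) as JSON.
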