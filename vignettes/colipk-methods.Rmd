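---
title: "Population pharmacokinetics of intravenous colistin sulfate: models and methods"
author: "colipk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of intravenous colistin sulfate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colipk)
```

## The problem

Colistin sulfate is the active (non-prodrug) form of colistin (polymyxin E),
dosed in million units (MU; 10,000 IU = 0.44 mg). In critically ill adults
its plasma exposure varies widely, and exposure drives both efficacy
(fAUC/MIC) and toxicity. `colipk` implements the full analysis pipeline a
population-PK study of this drug requires:

1. a structural **two-compartment IV-infusion model** with covariate
   equations, evaluated in closed form;
2. a **nonlinear mixed-effects estimation engine** (approximate marginal
   likelihood) with stepwise covariate modeling, bootstrap and a
   prediction-corrected visual predictive check;
3. **urinary-excretion analysis** (renal clearance, recovery percentage,
   renal fraction of total clearance);
4. **Monte Carlo dose-optimization** over regimens, renal-function strata
   and MICs;
5. **exposure-outcome ROC analysis**; and
6. a **virtual-study generator** so that every stage is testable without
   patient data.

## The structural and covariate model

Central-compartment concentration follows a linear two-compartment model
with zero-order infusion input. Individual parameters are

$$V = \mathrm{tvV}\, e^{\eta_V}, \qquad
  V_2 = \mathrm{tvV_2}\, (\mathrm{ALT}/\mathrm{ALT_{ref}})^{\theta_{ALT}},$$
$$CL = \mathrm{tvCL}\, (\mathrm{CrCL}/\mathrm{CrCL_{ref}})^{\theta_{CrCL}}\,
  e^{\eta_{CL}}, \qquad CL_2 = \mathrm{tvCL_2},$$

with log-normal inter-individual variability on $V$ and $CL$
($\eta \sim N(0, \omega^2)$) and a proportional residual-error model
$y = f\,(1+\varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$. The default
parameter set (`pop_params()`) is the published final estimate: tvV 16.1 L,
tvV2 50.5 L, tvCL 1.50 L/h, tvCL2 1.71 L/h, ALT exponent 0.635, CrCL
exponent 0.353, $\omega^2_V$ 0.0267, $\omega^2_{CL}$ 0.197, $\sigma$ 0.228,
with covariate references 57.5 ml/min and 37 U/L.

Neither $V_2$ nor $CL_2$ carries a random effect: the covariate equations
assign $\eta$'s only to $V$ and $CL$, and we apply that reading to both
peripheral parameters.

### Closed-form kinetics

The model is evaluated through its macro-exponential constants
($\alpha,\beta$ from $k_{10},k_{12},k_{21}$), superposing doses by
linearity; infusions enter through the cumulative bolus-kernel integral, so
concentrations *and* interval AUCs are analytic (no ODE solver, no
quadrature). This makes a 1,000-replicate Monte Carlo grid cheap and exact.
When $\alpha \to \beta$ (relative gap below $10^{-9}$) the evaluator
switches to the repeated-root limit expression. The test suite checks the
closed form against an independent matrix-exponential integrator on
randomized parameter/dose cases at $10^{-6}$ relative tolerance, and the
identity $AUC_{0-\infty} = D/CL$ exactly.

## Estimation engine

The marginal likelihood integrates the subject-level $\eta$'s by the
**Laplace approximation** around each subject's empirical-Bayes mode
(a FOCE-class objective). The published analysis used FOCE-ELS in a
proprietary tool; any deterministic approximate-marginal-likelihood scheme
is an acceptable substitute provided it passes the calibration tests
(parameter recovery, AIC model-selection direction, chi-square behaviour of
the covariate-inclusion test), which the suite verifies.

Numerical choices that matter:

* **Inner problem.** Per subject, a damped Newton search over $\eta$ with
  finite-difference derivatives, trust-region cap and Levenberg damping;
  stopping at objective change $<10^{-10}$. The final Hessian is
  Richardson-extrapolated, since its log-determinant enters the objective
  directly. Modes are warm-started from the previous outer iteration.
* **Outer problem.** Quasi-Newton (`nlminb`) on log-transformed typical
  values, variances and residual SDs (covariate coefficients unconstrained),
  with an explicit central-difference gradient (step $10^{-4}$) because the
  inner optimisation leaves ~$10^{-6}$ noise on the objective that defeats
  `nlminb`'s own forward differences near warm starts.
* **Convergence.** Declared when the optimizer reports success or a restart
  from the solution improves the objective by less than 0.05 — far below
  the $\chi^2$ decision thresholds (3.84 / 6.63) used anywhere downstream.
* **Standard errors** come from the finite-difference Hessian of the outer
  objective (delta method back to the natural scale; CV% = 100 SE/estimate);
  a sandwich estimator is out of scope. Shrinkage is
  $1 - SD(\hat\eta)/\omega$.
* **Covariate centering.** Continuous covariates are normalised by their
  *dataset median*, recomputed per dataset (57.5 ml/min and 37 U/L are the
  source cohort's values). `neg2ll()` called with a `pop_params` object uses
  that object's own references instead, so the objective is deterministic in
  its inputs.
* **BLQ handling.** Samples below the total-drug LLOQ (0.034 + 0.059 =
  0.093 mg/L) are flagged on ingest and excluded from fitting with a
  warning. A likelihood-based (M3) treatment is deliberately out of scope;
  at the exposures simulated here BLQ samples are rare (a few per ~100).

### Stepwise covariate modeling

Forward selection accepts the candidate with the largest OFV drop when
$\Delta OFV > 3.84$ ($\chi^2_1$, p = 0.05); backward elimination removes any
covariate whose deletion raises the OFV by $\le 6.63$ (p = 0.01). Ties break
by fewest added parameters, then lexicographically. Continuous candidates
enter as power functions, sex as an exponential-categorical effect; by
default all continuous candidates are tested on CL and V2 and sex on CL
(which parameters the source analysis tested per covariate is not stated;
this map is our documented choice). Candidates with missing values for any
subject are skipped with a warning.

## Urinary excretion

Renal clearance is noncompartmental: $CL_R = A_e / AUC$ with $A_e$ the
amount recovered over the collection interval and the plasma AUC taken as a
**linear trapezoid on the observed samples** over the same period (the
model-based AUC is available separately for sensitivity checks; which AUC
the source analysis used per patient is unstated, so the trapezoid is our
documented choice). Recovery is $100 A_e/\text{dose}$, with doses prorated
by the overlap of their dosing interval with the collection window, and the
renal fraction is $100\,CL_R/CL$. The cumulative excretion curve is
non-decreasing and bounded by 100%.

## Monte Carlo dose-optimization

Twelve regimens (loading 1.0 / 1.5 MU / none $\times$ 0.5 MU q12h, 0.5 MU
q8h, 0.75 MU q12h, 1.0 MU q12h; all 2-h infusions) are simulated at CrCL
$\in \{10, 50, 80, 120\}$ ml/min and MIC $\in \{0.5, 1, 2\}$ mg/L with 1,000
replicates by default. Targets: PTA of $fAUC/MIC \ge 20$ with $f = 0.49$
(PTA $\ge 90\%$ adequate), and $C_{ss,avg}$ rules $P(\ge 2\,\mathrm{mg/L}) >
80\%$ (efficacy) and $P(\ge 4\,\mathrm{mg/L}) < 30\%$ (toxicity).

Design choices:

* $C_{ss,avg}$ is the AUC of the dosing interval ending at 72 h divided by
  $\tau$ ("day 3"); day-1 AUC (0-24 h) feeds the day-1 PTA. Because the
  terminal half-life of the typical subject is ~48 h, day 3 is *not* true
  steady state; the infinite-time value daily dose/(24 CL) is exposed
  alongside (`css_avg_inf`) and is the quantity with the closed-form
  log-normal tail used by the property tests. Published attainment tables
  are treated as qualitative ordering references only, since the exact
  extraction convention behind them is underdetermined.
* Replicates draw $(\eta_V, \eta_{CL})$ only; residual (assay) error is not
  added, exposure being a model quantity, and parameter uncertainty is not
  resampled.
* ALT is fixed at 37 U/L: $V_2$ does not affect steady-state AUC; only
  transient day-1 metrics are (slightly) sensitive to this.
* The full grid reuses one $\eta$ draw per scenario (common random
  numbers), so the monotone ordering of cells in dose, CrCL and MIC is not
  blurred by Monte Carlo noise; this is why a few hundred replicates
  suffice for the ordering checks.

## Exposure-outcome analysis

ROC curves sweep every distinct threshold descending with ties grouped; the
area equals the Mann-Whitney statistic with ties counted ½ (verified against
an exhaustive-pairs oracle). The accompanying significance test is a
Wilcoxon rank-sum comparison of the metric between outcome groups — the
source analysis does not name its test, so this choice is documented here.
Patients on empirical therapy (no causative MIC) are excluded from AUC/MIC
analysis.

## The virtual-study generator

`generate_study()` emulates a critically-ill TDM cohort: 20 patients; CrCL
6.5-193.8 ml/min, ALT 7-495 U/L, weight 45-65 kg, age 18-92 y; daily
maintenance 1.0/1.5/2.0 MU (mix 10/70/20%) as 2-3 infusions of 1-2 h, a 1 MU
loading dose in 4 of 20 patients; sampling after 72 h of therapy with
trough/peak/random mix 38:27:33 (the exact fractions of the ~98-sample
cohort); a richly sampled arm of 6 patients (6-8 samples, others 3-5); and a
12-h urine collection in the rich (catheterised) 6.

Choices worth noting:

* **Covariates** are drawn log-uniformly within their ranges, *stratified*
  so exactly half the cohort falls on each side of the reported median
  (48.8 ml/min CrCL, 37.5 U/L ALT, ...). A plain log-uniform draw would put
  the sample median near the geometric mid-range (35.5 ml/min for CrCL) and,
  because the density of a wide log-uniform is low near its median, would
  leave the realized cohort median — and with it the dataset-median
  normalisers of the fit — very noisy. Stratification pins the median
  without changing the within-range law.
* **Sampling jitter**: troughs are 5 min pre-dose and peaks 5 min
  post-infusion-end, mimicking TDM practice.
* **Urine**: the 0-12 h collection window (72-84 h) is partitioned into 6-8
  sub-intervals; the amount in each is $CL_{R,true} \times$ the model AUC of
  the sub-interval, with $CL_{R,true}/CL$ log-uniform on 0.02-0.32 so
  recovery spans ~2-32% of dose. Two plasma samples of the rich arm are
  relocated to the window bounds so the noncompartmental AUC spans the
  collection interval (as bedside sampling for an excretion study would).
* **Outcomes**: a causative MIC (0.5/1/2 mg/L) is assigned to 80% of
  patients and the odds of a *valid* outcome rise with log fAUC/MIC — enough
  structure to exercise the ROC stage; no claim of clinical realism beyond
  the direction of the association.
* What a green test does **not** establish: the generator draws one covariate
  value per patient (no time-varying renal function), no CRRT, no
  co-medication, and residual error is strictly proportional — conclusions
  about those features of real data are out of reach by construction.

## Parameter-recovery protocol

The headline self-check simulates 200 virtual patients per seed from the
published estimates (0.75 MU q12h as 2-h infusions; 8 samples across the
60-72 h interval at 59.95, 61, 62, 62.25, 62.75, 64, 67, 71.5 h — trough,
on-infusion, end-of-infusion, early distribution and elimination), refits,
and takes the median over 10 seeds. The cohort's covariate medians are
calibrated to the truth's references (57.5 ml/min, 37 U/L) so that the
dataset-median normalisation of the fit targets the published typical
values; `scripts/acceptance.R` runs exactly this protocol.

## Known limitations

* The Laplace objective shares the usual small-sample biases of FOCE-class
  estimators; $\omega^2_V$ (true value 0.0267) is weakly identified even at
  the enriched design and is excluded from the recovery contract.
* Bootstrap refits reuse the point estimates as starting values; with very
  small cohorts individual resamples can fail to converge and are counted
  and excluded (more than 50% failures aborts).
* The pcVPC prediction-corrects by the bin median population prediction;
  bins with fewer than 3 observations are merged with a neighbour.
* One- and two-compartment structures only; no nonlinear elimination, no
  inter-occasion variability, no $\Omega$ off-diagonals.
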