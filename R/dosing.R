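# Monte Carlo dose-optimization: probability of target attainment on
# fAUC/MIC >= 20 (unbound fraction f = 0.49) and average steady-state
# concentration (Css,avg) attainment across regimens, renal-function strata
# and MICs.

#' The 12 simulated dosing regimens
#'
#' Loading dose of 1.0 MU, 1.5 MU or none, followed by 0.5 MU q12h,
#' 0.5 MU q8h, 0.75 MU q12h or 1.0 MU q12h; all infusions over 2 h.
#'
#' @return Named list of [regimen()]s.
#' @export
standard_regimens <- function() {
  maint <- list(list(0.5, 12), list(0.5, 8), list(0.75, 12), list(1.0, 12))
  loads <- list(NULL, 1.0, 1.5)
  regs <- list()
  for (m in maint) for (ld in loads) {
    r <- regimen(m[[1]], m[[2]], loading_dose = ld, infusion_duration = 2)
    regs[[format(r)]] <- r
  }
  regs
}

#' Define a Monte Carlo simulation scenario
#'
#' @param regimens Named list of [regimen()]s (default the 12 study
#'   regimens).
#' @param crcl_grid Renal-function strata, ml/min.
#' @param mic_grid MIC grid, mg/L.
#' @param n_replicates Replicates per cell (the study used 1,000).
#' @param f Unbound fraction of colistin.
#' @param pta_target fAUC/MIC target.
#' @param eval_days Evaluation days for the PTA (1 and/or 3).
#' @param alt ALT fixed in simulation (U/L); V2 does not affect steady-state
#'   AUC, so only transient day-1 metrics are sensitive to it.
#' @param seed Integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(regimens = standard_regimens(),
                         crcl_grid = c(10, 50, 80, 120),
                         mic_grid = c(0.5, 1, 2),
                         n_replicates = 1000, f = 0.49, pta_target = 20,
                         eval_days = c(1, 3), alt = 37, seed = 1) {
  stopifnot(f > 0, f <= 1, n_replicates >= 1, length(crcl_grid) > 0,
            length(mic_grid) > 0)
  structure(list(regimens = regimens, crcl_grid = crcl_grid,
                 mic_grid = mic_grid, n_replicates = n_replicates, f = f,
                 pta_target = pta_target, eval_days = eval_days, alt = alt,
                 seed = seed),
            class = "sim_scenario")
}

#' Simulate replicate exposures for one regimen and renal-function stratum
#'
#' Draws `(etaV, etaCL)` from their log-normal IIV distributions, holds CrCL
#' at the stratum value and ALT at its reference, and evaluates exposures via
#' the closed-form model. Residual (assay) error is not added: exposure is a
#' model quantity.
#'
#' @param pop A [pop_params()] set.
#' @param scenario A [sim_scenario()] (supplies `n_replicates` and `alt`).
#' @param crcl_value CrCL stratum (ml/min, > 0).
#' @param reg A [regimen()].
#' @param eta Optional `n x 2` matrix of pre-drawn `(etaV, etaCL)`; when
#'   supplied the random-number stream is untouched (common random numbers
#'   across grid cells).
#' @return Data frame, one row per replicate, with columns `auc_0_24_day1`,
#'   `auc_24_day3`, `css_min`, `css_max`, `css_avg`, `css_avg_inf`, `CL`.
#' @export
simulate_population <- function(pop, scenario, crcl_value, reg, eta = NULL) {
  stopifnot(crcl_value > 0)
  n <- scenario$n_replicates
  if (is.null(eta))
    eta <- cbind(rnorm(n, 0, sqrt(pop$omega2_V)),
                 rnorm(n, 0, sqrt(pop$omega2_CL)))
  cov <- covariates(crcl = crcl_value, alt = scenario$alt, weight = 55,
                    age = 60)
  rows <- lapply(seq_len(nrow(eta)), function(r) {
    ind <- individual_params(pop, cov, eta_V = eta[r, 1], eta_CL = eta[r, 2])
    m <- exposure_metrics(ind, reg, eval_day = 3)
    data.frame(auc_0_24_day1 = m$auc_0_24_day1, auc_24_day3 = m$auc_24_day3,
               css_min = m$css_min, css_max = m$css_max,
               css_avg = m$css_avg, css_avg_inf = m$css_avg_inf,
               CL = ind$CL)
  })
  do.call(rbind, rows)
}

#' Probability of target attainment on fAUC/MIC
#'
#' @param replicate_aucs 24-h AUCs per replicate (mg*h/L).
#' @param mic MIC (mg/L, > 0).
#' @param f Unbound fraction.
#' @param target fAUC/MIC target (default 20).
#' @return Attainment in percent.
#' @export
pta <- function(replicate_aucs, mic, f = 0.49, target = 20) {
  stopifnot(mic > 0)
  100 * mean(f * replicate_aucs / mic >= target)
}

#' Css,avg attainment probability
#' @param replicate_css_avg Average steady-state concentrations (mg/L).
#' @param threshold Threshold (mg/L, > 0); attainment counts values strictly
#'   above it.
#' @return Percent of replicates above the threshold.
#' @export
css_attainment <- function(replicate_css_avg, threshold) {
  stopifnot(threshold > 0)
  100 * mean(replicate_css_avg > threshold)
}

#' Run the full PTA / Css,avg simulation grid
#'
#' Uses common random numbers: one `(etaV, etaCL)` draw matrix per seed is
#' reused across every regimen, CrCL and MIC cell, so the monotone ordering
#' of the grid is not blurred by Monte Carlo noise.
#'
#' @param pop A [pop_params()] set (typically the final estimates).
#' @param scenario A [sim_scenario()].
#' @return A `pta_grid` list: `pta` (long data frame: regimen, crcl, mic,
#'   eval_day, pta), `css` (regimen, crcl, prob_over_2, prob_over_4,
#'   css_avg_median), `scenario`.
#' @export
run_simulation <- function(pop, scenario = sim_scenario()) {
  set.seed(scenario$seed)
  n <- scenario$n_replicates
  eta <- cbind(rnorm(n, 0, sqrt(pop$omega2_V)),
               rnorm(n, 0, sqrt(pop$omega2_CL)))
  pta_rows <- css_rows <- list()
  for (rn in names(scenario$regimens)) {
    reg <- scenario$regimens[[rn]]
    for (cr in scenario$crcl_grid) {
      ex <- simulate_population(pop, scenario, cr, reg, eta = eta)
      for (mic in scenario$mic_grid) for (day in scenario$eval_days) {
        aucs <- if (day == 1) ex$auc_0_24_day1 else ex$auc_24_day3
        pta_rows[[length(pta_rows) + 1L]] <- data.frame(
          regimen = rn, crcl = cr, mic = mic, eval_day = day,
          pta = pta(aucs, mic, scenario$f, scenario$pta_target))
      }
      css_rows[[length(css_rows) + 1L]] <- data.frame(
        regimen = rn, crcl = cr,
        prob_over_2 = css_attainment(ex$css_avg, 2),
        prob_over_4 = css_attainment(ex$css_avg, 4),
        css_avg_median = median(ex$css_avg))
    }
  }
  structure(list(pta = do.call(rbind, pta_rows),
                 css = do.call(rbind, css_rows), scenario = scenario),
            class = "pta_grid")
}

#' Decision rules for regimen adequacy
#' @param pta_threshold Required PTA, percent (default 90).
#' @param efficacy_threshold Required P(Css,avg >= 2 mg/L), percent (> 80).
#' @param toxicity_threshold Maximum P(Css,avg >= 4 mg/L), percent (< 30).
#' @return A `decision_rules` list.
#' @export
decision_rules <- function(pta_threshold = 90, efficacy_threshold = 80,
                           toxicity_threshold = 30) {
  stopifnot(pta_threshold > 0, pta_threshold <= 100,
            efficacy_threshold > 0, efficacy_threshold < 100,
            toxicity_threshold > 0, toxicity_threshold < 100)
  structure(list(pta_threshold = pta_threshold,
                 efficacy_threshold = efficacy_threshold,
                 toxicity_threshold = toxicity_threshold),
            class = "decision_rules")
}

#' Apply decision rules across the simulated grid
#'
#' A cell passes on PTA if PTA >= the threshold, on efficacy if
#' P(Css,avg >= 2) exceeds 80%, and on toxicity if P(Css,avg >= 4) stays
#' strictly below 30%; the composite verdict requires all applicable rules.
#'
#' @param grid A `pta_grid` from [run_simulation()].
#' @param rules A [decision_rules()] set.
#' @param mic MIC at which the PTA rule is evaluated (mg/L).
#' @param eval_day PTA evaluation day.
#' @return Data frame per (regimen, crcl): `pta_pass`, `efficacy_pass`,
#'   `toxicity_pass`, `verdict`.
#' @export
recommend <- function(grid, rules = decision_rules(), mic = 2, eval_day = 3) {
  pt <- grid$pta[grid$pta$mic == mic & grid$pta$eval_day == eval_day, ]
  if (nrow(pt) == 0) stop("no PTA cells for mic = ", mic, ", day = ",
                          eval_day, call. = FALSE)
  out <- merge(pt[, c("regimen", "crcl", "pta")], grid$css,
               by = c("regimen", "crcl"))
  miss <- nrow(grid$css) - nrow(out)
  if (miss > 0) stop(miss, " grid cell(s) missing", call. = FALSE)
  out$pta_pass <- out$pta >= rules$pta_threshold
  out$efficacy_pass <- out$prob_over_2 > rules$efficacy_threshold
  out$toxicity_pass <- out$prob_over_4 < rules$toxicity_threshold
  out$verdict <- out$pta_pass & out$efficacy_pass & out$toxicity_pass
  out
}

#' Read a simulation scenario from a JSON config
#'
#' Expected fields (all optional, defaults as in [sim_scenario()]):
#' `regimens` — array of objects with `maintenance_dose` (MU), `interval`
#' (h), optional `loading_dose` (MU) and `infusion_duration` (h);
#' `crcl_grid`, `mic_grid`, `n_replicates`, `f`, `pta_target`, `eval_days`,
#' `alt`, `seed`.
#'
#' @param path JSON file path.
#' @return A [sim_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- list()
  if (!is.null(cfg$regimens)) {
    regs <- list()
    for (r in cfg$regimens) {
      reg <- regimen(r$maintenance_dose, r$interval,
                     loading_dose = r$loading_dose,
                     infusion_duration = if (is.null(r$infusion_duration))
                       2 else r$infusion_duration)
      regs[[format(reg)]] <- reg
    }
    args$regimens <- regs
  }
  for (nm in c("crcl_grid", "mic_grid", "n_replicates", "f", "pta_target",
               "eval_days", "alt", "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  do.call(sim_scenario, args)
}

#' Closed-form attainment from the steady-state identity
#'
#' At true steady state `Css,avg = daily dose / (24 CL)` and CL is log-normal
#' given the CrCL stratum, so `P(Css,avg > c)` has a closed normal-tail form.
#' Used as the large-n limit of the Monte Carlo attainment.
#'
#' @param pop A [pop_params()] set.
#' @param crcl_value CrCL stratum (ml/min).
#' @param daily_dose_mg Daily maintenance dose (mg).
#' @param threshold Css,avg threshold (mg/L).
#' @return Probability in percent.
#' @export
css_attainment_closed_form <- function(pop, crcl_value, daily_dose_mg,
                                       threshold) {
  mu_cl <- log(pop$tvCL) + pop$dCLdCrCL * log(crcl_value / pop$crcl_ref)
  # Css > c  <=>  log CL < log(daily/(24 c))
  100 * stats::pnorm(log(daily_dose_mg / (24 * threshold)), mean = mu_cl,
                     sd = sqrt(pop$omega2_CL))
}

#' Write the simulation grid as CSVs
#' @param grid A `pta_grid`.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_simulation <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- file.path(dir, "pta_long.csv")
  write.csv(grid$pta, long, row.names = FALSE)
  css <- file.path(dir, "css_attainment.csv")
  write.csv(grid$css, css, row.names = FALSE)
  # Table-3-shaped pivot: regimens x CrCL for each threshold
  piv <- stats::reshape(grid$css[, c("regimen", "crcl", "prob_over_2")],
                        idvar = "regimen", timevar = "crcl",
                        direction = "wide")
  piv4 <- stats::reshape(grid$css[, c("regimen", "crcl", "prob_over_4")],
                         idvar = "regimen", timevar = "crcl",
                         direction = "wide")
  pivot <- file.path(dir, "css_pivot.csv")
  write.csv(merge(piv, piv4, by = "regimen"), pivot, row.names = FALSE)
  invisible(c(long, css, pivot))
}
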