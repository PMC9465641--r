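# Structural two-compartment IV-infusion model with covariate equations:
#   V  (L)   = tvV  * exp(etaV)
#   V2 (L)   = tvV2 * (ALT/alt_ref)^dV2dALT
#   CL (L/h) = tvCL * (CrCL/crcl_ref)^dCLdCrCL * exp(etaCL)
#   CL2(L/h) = tvCL2
# evaluated in closed form via the macro-exponential constants, superposing
# zero-order infusions by linearity.

#' Construct a population parameter set
#'
#' Fixed effects, covariate exponents, inter-individual variances and the
#' proportional residual SD of the covariate model, plus the covariate
#' normalisation references (cohort medians).
#'
#' @param tvV,tvV2 Typical central / peripheral distribution volumes (L).
#' @param tvCL,tvCL2 Typical central / inter-compartmental clearances (L/h).
#' @param dV2dALT Power exponent of ALT on V2 (dimensionless).
#' @param dCLdCrCL Power exponent of CrCL on CL (dimensionless).
#' @param omega2_V,omega2_CL Variances of the log-scale random effects on V
#'   and CL (>= 0).
#' @param sigma_prop Proportional residual-error SD (> 0).
#' @param crcl_ref,alt_ref Covariate normalisation references (ml/min, U/L).
#' @return A `pop_params` list.
#' @export
pop_params <- function(tvV = 16.1, tvV2 = 50.5, tvCL = 1.50, tvCL2 = 1.71,
                       dV2dALT = 0.635, dCLdCrCL = 0.353,
                       omega2_V = 0.0267, omega2_CL = 0.197,
                       sigma_prop = 0.228, crcl_ref = 57.5, alt_ref = 37) {
  stopifnot(tvV > 0, tvV2 > 0, tvCL > 0, tvCL2 > 0,
            omega2_V >= 0, omega2_CL >= 0, sigma_prop > 0,
            crcl_ref > 0, alt_ref > 0)
  structure(list(tvV = tvV, tvV2 = tvV2, tvCL = tvCL, tvCL2 = tvCL2,
                 dV2dALT = dV2dALT, dCLdCrCL = dCLdCrCL,
                 omega2_V = omega2_V, omega2_CL = omega2_CL,
                 sigma_prop = sigma_prop, crcl_ref = crcl_ref,
                 alt_ref = alt_ref),
            class = "pop_params")
}

#' Realise individual PK parameters from population values and covariates
#'
#' @param pop A [pop_params()] set.
#' @param cov A [covariates()] object (CrCL and ALT must be positive).
#' @param eta_V,eta_CL Log-scale random effects (0 gives the typical subject
#'   at reference covariates).
#' @return An `individual_params` list with `V`, `V2`, `CL`, `CL2`.
#' @export
individual_params <- function(pop, cov, eta_V = 0, eta_CL = 0) {
  if (cov$crcl <= 0 || cov$alt <= 0)
    stop("CrCL and ALT must be positive", call. = FALSE)
  structure(list(
    V   = pop$tvV * exp(eta_V),
    V2  = pop$tvV2 * (cov$alt / pop$alt_ref)^pop$dV2dALT,
    CL  = pop$tvCL * (cov$crcl / pop$crcl_ref)^pop$dCLdCrCL * exp(eta_CL),
    CL2 = pop$tvCL2), class = "individual_params")
}

as_dose_matrix <- function(doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  t0  <- vapply(doses, `[[`, numeric(1), "start_time")
  dur <- vapply(doses, `[[`, numeric(1), "infusion_duration")
  amt <- vapply(doses, `[[`, numeric(1), "amount")
  cbind(t0 = t0, dur = dur, amt = amt)
}

#' Simulate a concentration-time profile
#'
#' Central-compartment concentration of the linear two-compartment model with
#' zero-order infusion input, computed in closed form (exact for this model
#' class); repeated macro-roots are routed to the analytic limit.
#'
#' @param ind An [individual_params()] set.
#' @param doses List of [dose_event()]s.
#' @param times Evaluation times (hours, >= 0).
#' @param ncmt 1 or 2 compartments (2 is the study model; 1 ignores
#'   `V2`/`CL2`).
#' @return A `concentration_profile` data.frame with `time` and `conc` (mg/L).
#' @export
simulate_profile <- function(ind, doses, times, ncmt = 2) {
  stopifnot(all(times >= 0), ncmt %in% c(1, 2))
  dm <- as_dose_matrix(doses)
  conc <- cpp_conc(as.numeric(times), dm[, "t0"], dm[, "dur"], dm[, "amt"],
                   ind$V, if (ncmt == 2) ind$V2 else 1,
                   ind$CL, if (ncmt == 2) ind$CL2 else 0, as.integer(ncmt))
  structure(data.frame(time = as.numeric(times), conc = conc),
            class = c("concentration_profile", "data.frame"))
}

#' Analytic area under the concentration curve
#'
#' Integral of the closed-form concentration over `[t0, t1]`, evaluated as a
#' sum of exponential integrals (no numerical quadrature). `t1 = Inf` gives
#' the exact total exposure, `dose / CL` for a single dose.
#'
#' @param ind An [individual_params()] set.
#' @param doses List of [dose_event()]s.
#' @param t0,t1 Integration bounds in hours, `t1 > t0 >= 0` (`t1` may be
#'   `Inf`).
#' @param ncmt 1 or 2 compartments.
#' @return AUC in mg*h/L.
#' @export
model_auc <- function(ind, doses, t0, t1, ncmt = 2) {
  if (!(t1 > t0) || t0 < 0)
    stop("need t1 > t0 >= 0", call. = FALSE)
  dm <- as_dose_matrix(doses)
  if (is.infinite(t1)) {
    # total exposure: sum_i amt_i / CL minus exposure before t0
    total <- sum(dm[, "amt"]) / ind$CL
    if (t0 == 0) return(total)
    return(total - model_auc(ind, doses, 0, t0, ncmt))
  }
  cpp_auc(t0, t1, dm[, "t0"], dm[, "dur"], dm[, "amt"],
          ind$V, if (ncmt == 2) ind$V2 else 1,
          ind$CL, if (ncmt == 2) ind$CL2 else 0, as.integer(ncmt))
}

#' Steady-state exposure metrics for a regimen
#'
#' Evaluates trough, peak and average concentration on the dosing interval
#' ending at the evaluation time (day 1: hour 24; day 3: hour 72), plus the
#' day-1 (0-24 h) and day-3 (48-72 h) AUCs. `css_avg` is the AUC of the
#' evaluated interval divided by the interval length; `css_min` is the
#' concentration at the start of that interval (pre-dose) and `css_max` the
#' end-of-infusion concentration. The infinite-time average
#' `daily dose / (24 CL)` is also returned for reference.
#'
#' @param ind An [individual_params()] set.
#' @param reg A [regimen()].
#' @param eval_day Evaluation day (>= 1); metrics use the interval ending at
#'   `24 * eval_day` hours.
#' @return An `exposure_metrics` list: `auc_0_24_day1`, `auc_24_day3`,
#'   `css_min`, `css_max`, `css_avg`, `css_avg_inf`.
#' @export
exposure_metrics <- function(ind, reg, eval_day = 3) {
  stopifnot(eval_day >= 1)
  t_end <- 24 * eval_day
  doses <- regimen_doses(reg, horizon = t_end)
  tau <- reg$interval
  t_start <- t_end - tau
  auc_tau <- model_auc(ind, doses, t_start, t_end)
  cmin <- simulate_profile(ind, doses, t_start - 1e-9)$conc
  t_inf_end <- t_start + reg$infusion_duration
  cmax <- simulate_profile(ind, doses, t_inf_end)$conc
  structure(list(
    auc_0_24_day1 = model_auc(ind, doses, 0, min(24, t_end)),
    auc_24_day3 = if (t_end >= 72) model_auc(ind, doses, 48, 72) else NA_real_,
    css_min = cmin, css_max = cmax, css_avg = auc_tau / tau,
    css_avg_inf = daily_dose_mg(reg) / (24 * ind$CL)),
    class = "exposure_metrics")
}

#' Export concentration profiles as tidy CSV (ID, TIME, CONC)
#' @param profiles Named list of `concentration_profile` data frames (names
#'   are used as IDs).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile"))
    profiles <- list(`1` = profiles)
  df <- do.call(rbind, lapply(names(profiles), function(id)
    data.frame(ID = id, TIME = profiles[[id]]$time,
               CONC = profiles[[id]]$conc)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write population parameter sets as JSON
#' @param pop A [pop_params()] set.
#' @param path JSON path.
#' @return `path` invisibly (write); a `pop_params` object (read).
#' @export
write_pop_params <- function(pop, path) {
  jsonlite::write_json(unclass(pop), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pop_params
#' @export
read_pop_params <- function(path) {
  do.call(pop_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Apply proportional residual (assay) error to a model concentration
#'
#' `conc * (1 + eps)` with `eps ~ N(0, sigma_prop^2)`; negative draws are
#' truncated at zero and counted in a warning.
#'
#' @param conc Model concentrations (mg/L, >= 0).
#' @param sigma_prop Proportional residual SD (>= 0).
#' @return Observed concentrations, same length as `conc`.
#' @export
add_residual_error <- function(conc, sigma_prop) {
  stopifnot(all(conc >= 0), sigma_prop >= 0)
  obs <- conc * (1 + rnorm(length(conc), 0, sigma_prop))
  ntrunc <- sum(obs < 0)
  if (ntrunc > 0) {
    warning(ntrunc, " negative concentration draw(s) truncated at 0",
            call. = FALSE)
    obs[obs < 0] <- 0
  }
  obs
}
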