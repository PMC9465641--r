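#' @useDynLib colipk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd setNames nlminb
#'   wilcox.test approx
#' @importFrom utils head read.csv write.csv
NULL

# Total-colistin assay lower limits of quantification (mg/L): colistin A and
# colistin B are assayed separately and summed, so the total-drug limit is the
# sum of the two component limits.
LLOQ_A <- 0.034
LLOQ_B <- 0.059

#' Default assay configuration
#'
#' Lower limits of quantification of the LC-MS/MS assay for the two colistin
#' components. Total-drug samples below `lloq_total = lloq_A + lloq_B` are
#' flagged as below the limit of quantification (BLQ) on ingest.
#'
#' @return A list with `lloq_A`, `lloq_B` and `lloq_total` (mg/L).
#' @export
assay_config <- function() {
  list(lloq_A = LLOQ_A, lloq_B = LLOQ_B, lloq_total = LLOQ_A + LLOQ_B)
}

#' Convert a colistin sulfate dose from million units to milligrams
#'
#' Colistin sulfate is labelled in international units; 10,000 IU correspond
#' to 0.44 mg, i.e. 44 mg per million units (MU).
#'
#' @param dose_mu Dose in million units (MU); non-negative.
#' @return Dose in mg.
#' @examples
#' mu_to_mg(0.5)  # 22 mg
#' @export
mu_to_mg <- function(dose_mu) {
  if (!is.numeric(dose_mu) || any(!is.finite(dose_mu)) || any(dose_mu < 0))
    stop("dose_mu must be a non-negative finite number", call. = FALSE)
  dose_mu * 44.0
}

#' Cockcroft-Gault creatinine clearance
#'
#' CrCL = (140 - age) x weight / (72 x SCr), multiplied by 0.85 for females.
#'
#' @param age Age in years (positive, < 140).
#' @param weight Total body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Estimated creatinine clearance in ml/min.
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(scr <= 0)) stop("serum creatinine must be positive", call. = FALSE)
  if (any(age <= 0) || any(age >= 140)) stop("age must be in (0, 140)", call. = FALSE)
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  crcl <- (140 - age) * weight / (72 * scr)
  ifelse(sex == "female", 0.85 * crcl, crcl)
}

#' Total colistin concentration from the two assayed components
#'
#' Colistin A and colistin B have near-identical structure and kinetics; their
#' plasma concentrations are summed and the total is modelled as one analyte.
#'
#' @param conc_A,conc_B Component concentrations (mg/L), non-negative.
#' @return Total colistin concentration (mg/L).
#' @export
total_colistin <- function(conc_A, conc_B) {
  if (any(conc_A < 0) || any(conc_B < 0))
    stop("component concentrations must be non-negative", call. = FALSE)
  conc_A + conc_B
}

#' Construct a dosing event
#'
#' @param start_time Hours since the patient's first dose (>= 0).
#' @param amount Dose amount in mg (> 0).
#' @param infusion_duration Infusion duration in hours (> 0).
#' @return A `dose_event` list.
#' @export
dose_event <- function(start_time, amount, infusion_duration) {
  stopifnot(start_time >= 0, amount > 0, infusion_duration > 0)
  structure(list(start_time = start_time, amount = amount,
                 infusion_duration = infusion_duration),
            class = "dose_event")
}

#' Construct a plasma sample record
#'
#' @param time Hours since first dose.
#' @param concentration Total colistin concentration (mg/L, >= 0).
#' @param sample_class One of `"trough"`, `"peak"`, `"random"`.
#' @param config Assay configuration, see [assay_config()]; sets the BLQ flag.
#' @return A `plasma_sample` list with a `below_lloq` flag.
#' @export
plasma_sample <- function(time, concentration,
                          sample_class = c("random", "trough", "peak"),
                          config = assay_config()) {
  sample_class <- match.arg(sample_class)
  stopifnot(time >= 0, concentration >= 0)
  structure(list(time = time, concentration = concentration,
                 sample_class = sample_class,
                 below_lloq = concentration < config$lloq_total),
            class = "plasma_sample")
}

#' Construct a timed urine-collection interval
#'
#' @param start_time,end_time Interval bounds in hours since first dose
#'   (`end_time > start_time`).
#' @param volume Urine volume over the interval (L, >= 0).
#' @param concentration Total colistin concentration in the pooled urine
#'   (mg/L, >= 0).
#' @return A `urine_interval` list.
#' @export
urine_interval <- function(start_time, end_time, volume, concentration) {
  stopifnot(end_time > start_time, volume >= 0, concentration >= 0)
  structure(list(start_time = start_time, end_time = end_time,
                 volume = volume, concentration = concentration),
            class = "urine_interval")
}

#' Construct a patient covariate set
#'
#' CrCL and ALT are mandatory (they enter the final model); the remaining
#' candidate covariates live in `extras` and may be missing, in which case
#' they are dropped from covariate-selection candidacy for that run.
#'
#' @param crcl Creatinine clearance (ml/min, > 0).
#' @param alt Alanine aminotransferase (U/L, > 0).
#' @param weight Total body weight (kg, > 0).
#' @param age Age (years, >= 18).
#' @param sex `"male"` or `"female"`.
#' @param extras Named list of additional candidate covariates (AST, ALB, ...).
#' @return A `covariates` list.
#' @export
covariates <- function(crcl, alt, weight, age, sex = "male", extras = list()) {
  stopifnot(crcl > 0, alt > 0, weight > 0, age >= 18)
  sex <- match.arg(sex, c("male", "female"))
  structure(list(crcl = crcl, alt = alt, weight = weight, age = age,
                 sex = sex, extras = extras),
            class = "covariates")
}

#' Construct a patient record
#'
#' @param patient_id Identifier (scalar).
#' @param covariates A [covariates()] object.
#' @param doses Non-empty list of [dose_event()]s.
#' @param plasma List of [plasma_sample()]s (times non-decreasing).
#' @param urine List of [urine_interval()]s (possibly empty).
#' @param outcome_label Optional `"valid"` / `"invalid"` clinical outcome.
#' @return A `patient_record` list.
#' @export
patient_record <- function(patient_id, covariates, doses, plasma = list(),
                           urine = list(), outcome_label = NULL) {
  if (length(doses) == 0) stop("at least one dose is required", call. = FALSE)
  pt <- vapply(plasma, `[[`, numeric(1), "time")
  if (length(pt) && (any(pt < 0) || is.unsorted(pt)))
    stop("plasma sample times must be non-negative and non-decreasing",
         call. = FALSE)
  if (!is.null(outcome_label))
    outcome_label <- match.arg(outcome_label, c("valid", "invalid"))
  structure(list(patient_id = patient_id, covariates = covariates,
                 doses = doses, plasma = plasma, urine = urine,
                 outcome_label = outcome_label),
            class = "patient_record")
}

#' Construct a dosing regimen
#'
#' Regimens are expressed in million units (MU) at the interface and converted
#' to mg once, via the fixed 44 mg/MU factor, when doses are expanded.
#'
#' @param maintenance_dose Maintenance dose per administration (MU, > 0).
#' @param interval Dosing interval in hours, 8 or 12.
#' @param loading_dose Optional loading dose (MU) given as the first infusion.
#' @param infusion_duration Infusion duration in hours (default 2).
#' @return A `regimen` list.
#' @export
regimen <- function(maintenance_dose, interval, loading_dose = NULL,
                    infusion_duration = 2) {
  stopifnot(maintenance_dose > 0, interval %in% c(8, 12),
            infusion_duration > 0)
  if (!is.null(loading_dose)) stopifnot(loading_dose > 0)
  structure(list(loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose, interval = interval,
                 infusion_duration = infusion_duration),
            class = "regimen")
}

#' @export
format.regimen <- function(x, ...) {
  ld <- if (is.null(x$loading_dose)) "" else
    sprintf("%gMU + ", x$loading_dose)
  sprintf("%s%gMU q%dh", ld, x$maintenance_dose, as.integer(x$interval))
}

#' @export
print.regimen <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Expand a regimen into dose events
#'
#' The loading dose (if any) is the first infusion; maintenance doses follow
#' every `interval` hours starting at time 0 (or at `interval` when a loading
#' dose occupies time 0).
#'
#' @param reg A [regimen()].
#' @param horizon End of the dosing window (hours).
#' @return List of [dose_event()]s with amounts in mg.
#' @export
regimen_doses <- function(reg, horizon = 72) {
  stopifnot(inherits(reg, "regimen"), horizon > 0)
  doses <- list()
  t0 <- 0
  if (!is.null(reg$loading_dose)) {
    doses[[1]] <- dose_event(0, mu_to_mg(reg$loading_dose),
                             reg$infusion_duration)
    t0 <- reg$interval
  }
  k <- 0:ceiling((horizon - t0) / reg$interval)
  times <- t0 + reg$interval * k
  times <- times[times < horizon - 1e-6]
  for (tt in times)
    doses[[length(doses) + 1L]] <-
      dose_event(tt, mu_to_mg(reg$maintenance_dose), reg$infusion_duration)
  doses
}

#' Daily maintenance dose of a regimen in mg
#' @param reg A [regimen()].
#' @return Daily maintenance dose (mg).
#' @export
daily_dose_mg <- function(reg) {
  mu_to_mg(reg$maintenance_dose) * 24 / reg$interval
}
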