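# Independent numerical oracles and shared fixtures for the suite.

# Matrix-exponential solution of the two-compartment infusion system:
# algorithmically independent of the package's closed-form (eigenvalue)
# evaluator. State (A1, A2) with constant input during each infusion is
# propagated exactly via expm of the augmented constant-input system.
expm_conc <- function(times, doses, V, V2, CL, CL2, ncmt = 2) {
  k10 <- CL / V
  if (ncmt == 2) {
    k12 <- CL2 / V; k21 <- CL2 / V2
    A <- matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
  } else {
    A <- matrix(-k10, 1, 1)
  }
  d <- nrow(A)
  ev <- sort(unique(c(0, unlist(lapply(doses, function(dd)
    c(dd$start_time, dd$start_time + dd$infusion_duration))), times)))
  rate_at <- function(t) sum(vapply(doses, function(dd)
    if (t >= dd$start_time && t < dd$start_time + dd$infusion_duration)
      dd$amount / dd$infusion_duration else 0, numeric(1)))
  x <- numeric(d)
  out <- numeric(length(times))
  tcur <- 0
  for (t2 in ev) {
    if (t2 > tcur) {
      r <- rate_at((tcur + t2) / 2)
      aug <- rbind(cbind(A, c(r, numeric(d - 1))), 0)
      M <- as.matrix(Matrix::expm(aug * (t2 - tcur)))
      x <- (M %*% c(x, 1))[seq_len(d)]
      tcur <- t2
    }
    out[times == t2] <- x[1] / V
  }
  out
}

# dense-grid trapezoid (quadrature oracle for the analytic AUC)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# virtual study at the enriched parameter-recovery design: fixed 0.75 MU
# q12h regimen (2-h infusions), 8 samples across the 60-72 h interval
# covering trough, infusion, distribution and elimination phases
recovery_design <- function(n_patients, seed, ...) {
  study_design(
    n_patients = n_patients,
    covariate_ranges = list(crcl = c(6.5, 193.8, 57.5),
                            alt = c(7, 495, 37),
                            weight = c(45, 65, NA), age = c(18, 92, NA)),
    regimen_fixed = regimen(0.75, 12, infusion_duration = 2),
    sample_times = c(59.95, 61, 62, 62.25, 62.75, 64, 67, 71.5),
    urine_subset_size = 0, horizon = 72, seed = seed, ...)
}

# small two-patient study built by hand (dataset-dialect fixture)
tiny_study <- function() {
  cov1 <- covariates(crcl = 60, alt = 30, weight = 55, age = 60, sex = "male")
  cov2 <- covariates(crcl = 25, alt = 120, weight = 50, age = 70,
                     sex = "female", extras = list(alb = 28))
  p1 <- patient_record(1, cov1,
    doses = list(dose_event(0, 33, 2), dose_event(12, 33, 2)),
    plasma = list(plasma_sample(11.9, 0.8, "trough"),
                  plasma_sample(14.1, 2.4, "peak"),
                  plasma_sample(20, 1.2, "random")))
  p2 <- patient_record(2, cov2,
    doses = list(dose_event(0, 22, 1), dose_event(12, 22, 1)),
    plasma = list(plasma_sample(11.9, 1.5, "trough"),
                  plasma_sample(13.1, 3.0, "peak"),
                  plasma_sample(18, 2.0, "random")),
    urine = list(urine_interval(0, 6, 0.8, 2.0),
                 urine_interval(6, 12, 1.0, 1.5)),
    outcome_label = "valid")
  structure(list(p1, p2), class = "colipk_study")
}

table1_ranges <- function() {
  list(crcl = c(6.5, 193.8, 48.8), alt = c(7, 495, 37.5),
       weight = c(45, 65, 55), age = c(18, 92, 60.5),
       alb = c(22.2, 43.3, 30.8))
}
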