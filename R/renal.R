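# Urinary-recovery and renal-clearance analysis over a collection interval.
# CL_R = amount excreted / plasma AUC over the same period (noncompartmental,
# linear trapezoid on the observed samples).

#' Total amount of colistin excreted over urine-collection intervals
#'
#' @param intervals List of [urine_interval()]s, non-overlapping.
#' @return Amount in mg (`sum(volume * concentration)`).
#' @export
urinary_amount <- function(intervals) {
  if (length(intervals) == 0) return(0)
  st <- vapply(intervals, `[[`, numeric(1), "start_time")
  en <- vapply(intervals, `[[`, numeric(1), "end_time")
  o <- order(st)
  if (any(st[o][-1] < en[o][-length(en)] - 1e-9))
    stop("urine intervals overlap", call. = FALSE)
  sum(vapply(intervals, function(u) u$volume * u$concentration, numeric(1)))
}

#' Urinary recovery as a percentage of the administered dose
#' @param amount Amount excreted (mg).
#' @param dose_in_window Dose administered over the collection window (mg, > 0).
#' @return Recovery in percent.
#' @export
recovery_percent <- function(amount, dose_in_window) {
  if (dose_in_window <= 0) stop("dose must be positive", call. = FALSE)
  100 * amount / dose_in_window
}

#' Trapezoidal AUC of observed plasma samples over an interval
#'
#' Linear-up/linear-down trapezoid on the observed concentrations; sample
#' times must span the interval.
#'
#' @param times,concs Observed sample times (h) and concentrations (mg/L).
#' @param t0,t1 Interval bounds.
#' @return AUC in mg*h/L.
#' @export
trapezoid_auc <- function(times, concs, t0, t1) {
  stopifnot(length(times) == length(concs), t1 > t0)
  o <- order(times)
  times <- times[o]; concs <- concs[o]
  if (min(times) > t0 + 1e-9 || max(times) < t1 - 1e-9)
    stop(sprintf(
      "plasma samples (%.3g-%.3g h) do not span the interval [%.3g, %.3g] h",
      min(times), max(times), t0, t1), call. = FALSE)
  g <- approx(times, concs, xout = sort(unique(c(t0, t1,
         times[times >= t0 & times <= t1]))), ties = "ordered")
  sum(diff(g$x) * (head(g$y, -1) + g$y[-1]) / 2)
}

#' Renal clearance from urinary amount and plasma AUC over the same period
#' @param amount Amount excreted in urine (mg).
#' @param plasma_auc_same_interval Plasma AUC over the collection interval
#'   (mg*h/L, > 0).
#' @return Renal clearance in L/h.
#' @export
renal_clearance <- function(amount, plasma_auc_same_interval) {
  if (plasma_auc_same_interval <= 0) stop("AUC must be positive",
                                          call. = FALSE)
  amount / plasma_auc_same_interval
}

#' Renal fraction of total clearance
#' @param cl_renal Renal clearance (L/h).
#' @param cl_total Total body clearance (L/h, > 0).
#' @return Percent of total clearance; values above 100 indicate inconsistent
#'   inputs and trigger a warning but are still returned.
#' @export
fraction_renal <- function(cl_renal, cl_total) {
  if (cl_total <= 0) stop("total clearance must be positive", call. = FALSE)
  fr <- 100 * cl_renal / cl_total
  if (any(fr > 100))
    warning("renal fraction exceeds 100%; inputs are inconsistent",
            call. = FALSE)
  fr
}

dose_in_window <- function(doses, t0, t1) {
  # doses prorated by overlap of their dosing interval with [t0, t1]; the
  # interval of a dose runs to the next dose (or the same spacing past the
  # last)
  st <- sort(vapply(doses, `[[`, numeric(1), "start_time"))
  amt <- vapply(doses, `[[`, numeric(1), "amount")[
    order(vapply(doses, `[[`, numeric(1), "start_time"))]
  spacing <- if (length(st) > 1) diff(st) else 12
  ends <- c(st[-1], st[length(st)] + spacing[length(spacing)])
  ov <- pmax(0, pmin(ends, t1) - pmax(st, t0)) / (ends - st)
  sum(amt * ov)
}

#' Per-patient renal summary
#'
#' Computes the excreted amount, the recovery as % of the prorated dose over
#' the collection window, the renal clearance against the trapezoidal plasma
#' AUC over the same period, the renal fraction of an individual's total
#' clearance, and the cumulative excretion curve over the intervals.
#'
#' @param patient A [patient_record()] with urine intervals and plasma samples
#'   spanning the collection window.
#' @param cl_total The patient's total body clearance (L/h), e.g. from the
#'   fitted model.
#' @return A `renal_summary` list.
#' @export
renal_summary <- function(patient, cl_total) {
  if (length(patient$urine) == 0)
    stop("patient has no urine collections", call. = FALSE)
  st <- vapply(patient$urine, `[[`, numeric(1), "start_time")
  en <- vapply(patient$urine, `[[`, numeric(1), "end_time")
  t0 <- min(st); t1 <- max(en)
  amt <- urinary_amount(patient$urine)
  dose <- dose_in_window(patient$doses, t0, t1)
  times <- vapply(patient$plasma, `[[`, numeric(1), "time")
  concs <- vapply(patient$plasma, `[[`, numeric(1), "concentration")
  auc <- trapezoid_auc(times, concs, t0, t1)
  clr <- renal_clearance(amt, auc)
  o <- order(st)
  cum <- cumsum(vapply(patient$urine[o], function(u)
    u$volume * u$concentration, numeric(1)))
  structure(list(
    amount_excreted = amt,
    recovery_percent = recovery_percent(amt, dose),
    cl_renal = clr,
    fraction_renal = fraction_renal(clr, cl_total),
    cumulative_curve = data.frame(time = en[o],
                                  percent_of_dose = 100 * cum / dose)),
    class = "renal_summary")
}

#' Study-level renal report
#' @param study A `colipk_study`; only patients with urine data contribute.
#' @param cl_by_patient Named numeric vector of total clearances (L/h) keyed
#'   by patient id.
#' @return Data frame: one row per patient with amount, recovery %, CL_R and
#'   renal fraction.
#' @export
renal_report <- function(study, cl_by_patient) {
  rows <- list()
  for (p in study) {
    if (length(p$urine) == 0) next
    id <- as.character(p$patient_id)
    rs <- renal_summary(p, cl_by_patient[[id]])
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = id, amount_excreted = rs$amount_excreted,
      recovery_percent = rs$recovery_percent, cl_renal = rs$cl_renal,
      fraction_renal = rs$fraction_renal)
  }
  do.call(rbind, rows)
}
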