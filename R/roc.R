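# Exposure-outcome analysis: ROC curves and trapezoidal AUC_ROC relating
# steady-state exposure metrics (AUCss,0-24/MIC, Css,min/max/avg) to the
# binary clinical outcome (valid / invalid).

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  labels
}

#' ROC curve points
#'
#' Sweeps every distinct score threshold in descending order (ties grouped)
#' and returns the (FPR, TPR) path from (0, 0) to (1, 1).
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels Binary outcome, 1 = positive (valid), 0 = negative.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & scores >= t) / n0,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; equal to the Mann-Whitney U
#' statistic divided by `n1 * n0`, counting ties as 1/2.
#'
#' @inheritParams roc_curve
#' @return Scalar in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Mann-Whitney test of an exposure metric against the outcome
#'
#' Wilcoxon rank-sum comparison of the metric between outcome groups; used
#' both as the significance test accompanying AUC_ROC and for group-mean
#' style comparisons.
#'
#' @inheritParams roc_curve
#' @return `htest` object from [stats::wilcox.test()].
#' @export
roc_test <- function(scores, labels) {
  labels <- check_labels(labels)
  suppressWarnings(wilcox.test(scores[labels == 1], scores[labels == 0]))
}

#' Exposure-outcome table for a study
#'
#' Builds one row per evaluable patient with steady-state exposure metrics
#' from the individual model parameters and the patient's regimen, plus the
#' AUCss,0-24/MIC ratio. Patients without a causative-pathogen MIC (empirical
#' therapy) are excluded from the AUC/MIC analysis.
#'
#' @param study A `colipk_study` with `outcome_label`s.
#' @param pop A [pop_params()] set.
#' @param eta Optional `n x 2` matrix of per-patient `(etaV, etaCL)`
#'   empirical-Bayes estimates; zero when omitted.
#' @param mic_by_patient Named numeric vector of causative MICs keyed by
#'   patient id; patients absent from it get `NA` ratios.
#' @return Data frame of exposure-outcome rows.
#' @export
exposure_outcome_table <- function(study, pop, eta = NULL,
                                   mic_by_patient = NULL) {
  rows <- list()
  for (i in seq_along(study)) {
    p <- study[[i]]
    if (is.null(p$outcome_label)) next
    ev <- if (is.null(eta)) c(0, 0) else eta[i, ]
    ind <- individual_params(pop, p$covariates, ev[1], ev[2])
    # steady-state interval from the patient's own maintenance schedule
    st <- vapply(p$doses, `[[`, numeric(1), "start_time")
    tau <- if (length(st) > 1) median(diff(sort(st))) else 12
    amt <- p$doses[[length(p$doses)]]$amount
    dur <- p$doses[[length(p$doses)]]$infusion_duration
    reg <- regimen(amt / 44, tau, infusion_duration = dur)
    m <- exposure_metrics(ind, reg, eval_day = 3)
    auc24 <- amt * (24 / tau) / ind$CL  # steady-state daily AUC
    id <- as.character(p$patient_id)
    mic <- if (!is.null(mic_by_patient) && id %in% names(mic_by_patient))
      mic_by_patient[[id]] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = id, auc_mic_ratio = auc24 / mic,
      css_min = m$css_min, css_max = m$css_max, css_avg = m$css_avg,
      outcome = p$outcome_label)
  }
  do.call(rbind, rows)
}

#' Summarise ROC performance of each exposure metric
#'
#' @param tab Data frame from [exposure_outcome_table()] (or equivalent CSV).
#' @return Data frame: metric, n, auc_roc, p_value (Mann-Whitney).
#' @export
roc_summary <- function(tab) {
  metrics <- c("auc_mic_ratio", "css_min", "css_max", "css_avg")
  labels <- as.integer(tab$outcome == "valid")
  rows <- lapply(metrics, function(m) {
    ok <- !is.na(tab[[m]])
    if (sum(ok) < 2 || length(unique(labels[ok])) < 2)
      return(data.frame(metric = m, n = sum(ok), auc_roc = NA_real_,
                        p_value = NA_real_))
    data.frame(metric = m, n = sum(ok),
               auc_roc = auc_roc(tab[[m]][ok], labels[ok]),
               p_value = roc_test(tab[[m]][ok], labels[ok])$p.value)
  })
  do.call(rbind, rows)
}
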