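# Virtual-study generator: emulates a critically-ill TDM cohort (sparse
# trough/peak/random sampling after 72 h of therapy, skewed covariates, a
# urine-collection subset) so every pipeline stage is testable without
# patient data. The hidden truth (per-patient etas, true renal clearances,
# causative MICs) is returned alongside the records.

#' The published final-model estimates as the default simulation truth
#' @return A [pop_params()] set.
#' @export
generate_true_params <- function() pop_params()

# log-uniform draw on [lo, hi] with half the cohort on each side of `med`:
# piecewise log-uniform, stratified so the empirical median is pinned at the
# calibration point (a plain random split would leave the sample median very
# noisy, because the density of a wide log-uniform is low near its median)
rlogunif_med <- function(n, lo, hi, med = NULL) {
  if (is.null(med)) return(exp(runif(n, log(lo), log(hi))))
  side <- sample(rep(c(TRUE, FALSE), length.out = n))
  out <- numeric(n)
  out[side] <- exp(runif(sum(side), log(lo), log(med)))
  out[!side] <- exp(runif(sum(!side), log(med), log(hi)))
  out
}

#' Define a virtual study design
#'
#' Defaults reproduce the cohort shape of the source study: 20 critically
#' ill patients; CrCL 6.5-193.8 ml/min (median 48.8), ALT 7-495 U/L (median
#' 37.5), weight 45-65 kg, age 18-92 y; daily maintenance 1.0/1.5/2.0 MU
#' given as 2-3 infusions of 1-2 h with a loading dose in 4 of 20 patients;
#' plasma sampling after 72 h of therapy with trough/peak/random mix
#' 38:27:33; a rich-sampling arm of 6 patients (6-8 samples, others 3-5,
#' about 98 samples in total); and a 12-h urine collection in 6 patients.
#'
#' @param n_patients Number of virtual patients.
#' @param covariate_ranges Named list of `c(lo, hi, median)` per covariate
#'   (`median = NA` for plain log-uniform draws).
#' @param sampling_mix Probabilities of trough/peak/random samples (sum 1).
#' @param daily_dose_mix Named probabilities of the daily maintenance dose in
#'   MU.
#' @param n_loading Number of patients starting with a 1 MU loading dose.
#' @param n_rich Number of richly sampled patients.
#' @param rich_samples,sparse_samples Integer ranges of per-patient sample
#'   counts.
#' @param urine_subset_size Number of patients with a urine collection.
#' @param recovery_range Range of true urinary recovery as a fraction of
#'   dose (sets `CL_R_true / CL`).
#' @param true_params A [pop_params()] truth.
#' @param horizon Dosing horizon (h); sampling happens in `[72, horizon]`.
#' @param regimen_fixed Optional [regimen()] applied to every patient
#'   (overrides the dose mix).
#' @param sample_times Optional fixed sampling schedule (hours) applied to
#'   every patient (overrides the sampling mix and counts).
#' @param seed Integer seed.
#' @return A `study_design` list.
#' @export
study_design <- function(n_patients = 20,
                         covariate_ranges = list(
                           crcl = c(6.5, 193.8, 48.8),
                           alt = c(7, 495, 37.5),
                           weight = c(45, 65, 55),
                           age = c(18, 92, 60.5),
                           alb = c(22.2, 43.3, 30.8)),
                         sampling_mix = c(trough = 38, peak = 27,
                                          random = 33) / 98,
                         daily_dose_mix = c(`1` = 0.1, `1.5` = 0.7,
                                            `2` = 0.2),
                         n_loading = round(n_patients / 5),
                         n_rich = min(6, n_patients),
                         rich_samples = 6:8, sparse_samples = 3:5,
                         urine_subset_size = min(6, n_patients),
                         recovery_range = c(0.02, 0.32),
                         true_params = generate_true_params(),
                         horizon = 96, regimen_fixed = NULL,
                         sample_times = NULL, seed = 1) {
  if (abs(sum(sampling_mix) - 1) > 1e-9)
    stop("sampling_mix must sum to 1", call. = FALSE)
  if (abs(sum(daily_dose_mix) - 1) > 1e-9)
    stop("daily_dose_mix must sum to 1", call. = FALSE)
  stopifnot(n_patients >= 1, urine_subset_size <= n_patients,
            all(vapply(covariate_ranges, function(r) r[1] > 0, logical(1))))
  structure(list(n_patients = n_patients,
                 covariate_ranges = covariate_ranges,
                 sampling_mix = sampling_mix,
                 daily_dose_mix = daily_dose_mix, n_loading = n_loading,
                 n_rich = n_rich, rich_samples = rich_samples,
                 sparse_samples = sparse_samples,
                 urine_subset_size = urine_subset_size,
                 recovery_range = recovery_range, true_params = true_params,
                 horizon = horizon, regimen_fixed = regimen_fixed,
                 sample_times = sample_times, seed = seed),
            class = "study_design")
}

draw_regimen <- function(design) {
  if (!is.null(design$regimen_fixed)) return(design$regimen_fixed)
  daily <- as.numeric(sample(names(design$daily_dose_mix), 1,
                             prob = design$daily_dose_mix))
  interval <- sample(c(8, 12), 1)
  n_per_day <- 24 / interval
  regimen(daily / n_per_day, interval,
          infusion_duration = sample(1:2, 1))
}

classify_time <- function(t, doses) {
  st <- vapply(doses, `[[`, numeric(1), "start_time")
  en <- st + vapply(doses, `[[`, numeric(1), "infusion_duration")
  if (any(st > t & st - t <= 0.2)) return("trough")
  if (any(en <= t & t - en <= 0.2)) return("peak")
  "random"
}

#' Generate a virtual study
#'
#' Draws covariates (piecewise log-uniform within range, median-calibrated),
#' per-patient random effects from the truth's IIV variances, a dosing
#' history, plasma samples per the trough/peak/random mix with proportional
#' residual error, and urine collections for the renal subset with amounts
#' `CL_R_true x model AUC` over each sub-interval. Causative MICs and
#' outcome labels are attached for the exposure-outcome stage.
#'
#' @param design A [study_design()].
#' @return List with `study` (a `colipk_study`) and `truth` (per-patient
#'   `eta` matrix, `cl_r_true` and `mic` named vectors, `params`, `design`).
#' @export
generate_study <- function(design = study_design()) {
  set.seed(design$seed)
  pop <- design$true_params
  n <- design$n_patients
  cr <- design$covariate_ranges
  draw_cov <- function(nm) {
    r <- cr[[nm]]
    med <- if (length(r) >= 3 && is.finite(r[3])) r[3] else NULL
    rlogunif_med(n, r[1], r[2], med)
  }
  crcl <- draw_cov("crcl"); alt <- draw_cov("alt")
  weight <- draw_cov("weight"); age <- pmax(18, draw_cov("age"))
  alb <- if ("alb" %in% names(cr)) draw_cov("alb") else rep(NA_real_, n)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(.6, .4))
  eta <- cbind(eta_V = rnorm(n, 0, sqrt(pop$omega2_V)),
               eta_CL = rnorm(n, 0, sqrt(pop$omega2_CL)))
  rich_ids <- sample.int(n, design$n_rich)
  load_ids <- sample.int(n, min(design$n_loading, n))
  # the urine-collection subset is the richly sampled (catheterised) arm,
  # whose samples span the collection interval
  urine_ids <- if (design$urine_subset_size <= design$n_rich)
    rich_ids[seq_len(design$urine_subset_size)] else
    sample.int(n, design$urine_subset_size)
  cl_r_true <- setNames(rep(NA_real_, n), seq_len(n))
  mic <- setNames(rep(NA_real_, n), seq_len(n))
  study <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- draw_regimen(design)
    if (i %in% load_ids && is.null(reg$loading_dose))
      reg$loading_dose <- 1.0
    doses <- regimen_doses(reg, horizon = design$horizon)
    cov <- covariates(crcl[i], alt[i], weight[i], age[i], sex[i],
                      extras = if (is.na(alb[i])) list() else
                        list(alb = alb[i]))
    ind <- individual_params(pop, cov, eta[i, 1], eta[i, 2])
    st <- vapply(doses, `[[`, numeric(1), "start_time")
    en <- st + vapply(doses, `[[`, numeric(1), "infusion_duration")
    if (is.null(design$sample_times)) {
      nsamp <- if (i %in% rich_ids) sample(design$rich_samples, 1) else
        sample(design$sparse_samples, 1)
      cls <- sample(names(design$sampling_mix), nsamp, replace = TRUE,
                    prob = design$sampling_mix)
      win <- if (i %in% urine_ids) c(72, 84) else c(72, design$horizon)
      ts <- vapply(cls, function(cc) {
        if (cc == "trough") {
          cand <- st[st >= win[1] + 1/12 & st <= win[2]]
          if (length(cand)) return(sample(c(cand, cand), 1) - 1/12)
        } else if (cc == "peak") {
          cand <- en[en >= win[1] & en + 1/12 <= win[2]]
          if (length(cand)) return(sample(c(cand, cand), 1) + 1/12)
        }
        runif(1, win[1], win[2])
      }, numeric(1))
      if (i %in% urine_ids && nsamp >= 2) {
        # relocate two samples to the collection-window bounds so the
        # noncompartmental AUC spans the urine interval; a sample at the
        # dosing instant is a trough, so class labels stay truthful
        movable <- which(cls %in% c("trough", "random"))
        if (length(movable) < 2) movable <- seq_len(nsamp)
        ts[movable[1]] <- win[1]
        ts[movable[2]] <- win[2]
        cls[movable[1:2]] <- ifelse(cls[movable[1:2]] == "peak", "random",
                                    cls[movable[1:2]])
      }
    } else {
      ts <- design$sample_times
      cls <- vapply(ts, classify_time, character(1), doses)
    }
    o <- order(ts)
    ts <- ts[o]; cls <- cls[o]
    f <- simulate_profile(ind, doses, ts)$conc
    obs <- suppressWarnings(add_residual_error(f, pop$sigma_prop))
    plasma <- lapply(seq_along(ts), function(j)
      plasma_sample(ts[j], obs[j], cls[j]))
    urine <- list()
    if (i %in% urine_ids) {
      fr <- exp(runif(1, log(design$recovery_range[1]),
                      log(design$recovery_range[2])))
      cl_r <- fr * ind$CL
      cl_r_true[i] <- cl_r
      cuts <- sort(c(72, 84, 72 + 12 * runif(sample(5:7, 1))))
      for (k in seq_len(length(cuts) - 1)) {
        a <- cl_r * model_auc(ind, doses, cuts[k], cuts[k + 1])
        vol <- runif(1, 0.1, 0.4)
        urine[[k]] <- urine_interval(cuts[k], cuts[k + 1], vol, a / vol)
      }
    }
    # causative MIC for 80% of patients; outcome odds rise with fAUC/MIC
    outcome <- NULL
    if (runif(1) < 0.8) {
      mic[i] <- sample(c(0.5, 1, 2), 1, prob = c(.5, .3, .2))
      auc24 <- daily_dose_mg(reg) / ind$CL
      p_valid <- stats::plogis(1.5 * (log(0.49 * auc24 / mic[i]) - log(20)))
      outcome <- if (runif(1) < p_valid) "valid" else "invalid"
    }
    study[[i]] <- patient_record(i, cov, doses, plasma, urine, outcome)
  }
  list(study = structure(study, class = "colipk_study"),
       truth = list(eta = eta, cl_r_true = cl_r_true, mic = mic,
                    params = pop, design = design))
}

#' Write a generated study to disk
#'
#' Emits the event-dataset CSV, the urine CSV, and a JSON side-file with the
#' simulation truth.
#'
#' @param gen Output of [generate_study()].
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_study <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- file.path(dir, "events.csv")
  ur <- file.path(dir, "urine.csv")
  tr <- file.path(dir, "truth.json")
  write_dataset(gen$study, ev)
  write_urine(gen$study, ur)
  jsonlite::write_json(list(
    eta = gen$truth$eta, cl_r_true = gen$truth$cl_r_true,
    mic = gen$truth$mic, params = unclass(gen$truth$params),
    seed = gen$truth$design$seed),
    tr, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ev, ur, tr))
}
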