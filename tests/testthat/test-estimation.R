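# The likelihood oracle tests work on tiny designs where the marginal
# likelihood can be computed independently in R.

naive_neg2ll <- function(study, pop, spec = final_model_spec()) {
  # fixed-effects (eta = 0) -2LL with proportional error, computed directly
  tot <- 0
  for (p in study) {
    ind <- individual_params(pop, p$covariates)
    ts <- vapply(p$plasma, `[[`, numeric(1), "time")
    dv <- vapply(p$plasma, `[[`, numeric(1), "concentration")
    f <- simulate_profile(ind, p$doses, ts,
                          ncmt = spec$n_compartments)$conc
    v <- (pop$sigma_prop * f)^2
    tot <- tot + sum(log(2 * pi * v) + (dv - f)^2 / v)
  }
  tot
}

test_that("with zero IIV the objective is the fixed-effects likelihood", {
  gen <- generate_study(recovery_design(6, seed = 5))
  pop <- pop_params(omega2_V = 0, omega2_CL = 0)
  expect_equal(neg2ll(final_model_spec(), gen$study, pop),
               naive_neg2ll(gen$study, pop), tolerance = 1e-8)
})

test_that("one subject, one observation matches a 1-d Laplace oracle", {
  cov <- covariates(crcl = 80, alt = 50, weight = 55, age = 60)
  rec <- patient_record(1, cov, doses = list(dose_event(0, 33, 2)),
                        plasma = list(plasma_sample(5, 1.4, "random")))
  study <- structure(list(rec), class = "colipk_study")
  pop <- pop_params()
  spec <- model_spec(2, covariate_assignments = list(
    CL = list(crcl = "power"), V2 = list(alt = "power")), iiv = "CL")
  # independent 1-d Laplace: -2 log joint minimised over etaCL by optimize,
  # curvature by central finite differences. With a single subject the
  # dataset medians (the package's normalisers) equal the subject's own
  # covariate values, so the power terms drop out of the oracle.
  g <- function(eta) {
    ind <- structure(list(V = pop$tvV, V2 = pop$tvV2,
                          CL = pop$tvCL * exp(eta), CL2 = pop$tvCL2),
                     class = "individual_params")
    f <- simulate_profile(ind, rec$doses, 5)$conc
    v <- (pop$sigma_prop * f)^2
    log(2 * pi * v) + (1.4 - f)^2 / v +
      log(2 * pi * pop$omega2_CL) + eta^2 / pop$omega2_CL
  }
  opt <- optimize(g, c(-4, 4), tol = 1e-12)
  # curvature by Richardson-extrapolated central differences (steps large
  # enough to stay above second-difference roundoff)
  d2 <- function(h) (g(opt$minimum + h) - 2 * opt$objective +
                       g(opt$minimum - h)) / h^2
  H <- (4 * d2(5e-4) - d2(1e-3)) / 3
  oracle <- opt$objective + log(H) - log(4 * pi)
  params <- list(tvV = pop$tvV, tvV2 = pop$tvV2, tvCL = pop$tvCL,
                 tvCL2 = pop$tvCL2, dCLdCRCL = pop$dCLdCrCL,
                 dV2dALT = pop$dV2dALT, omega2_CL = pop$omega2_CL,
                 sigma_prop = pop$sigma_prop)
  got <- neg2ll(spec, study, params)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("fit recovers the truth on low-noise rich data within 2%", {
  pop <- pop_params(sigma_prop = 0.01)
  des <- study_design(
    n_patients = 50,
    covariate_ranges = list(crcl = c(6.5, 193.8, 57.5),
                            alt = c(7, 495, 37),
                            weight = c(45, 65, NA), age = c(18, 92, NA)),
    regimen_fixed = regimen(0.75, 12, infusion_duration = 2),
    sample_times = c(1, 2, 2.5, 4, 8, 11.9, 60, 61, 62, 62.5, 66, 71.5),
    urine_subset_size = 0, horizon = 72, true_params = pop, seed = 31)
  gen <- generate_study(des)
  fit <- suppressWarnings(fit_ppk(final_model_spec(), gen$study,
                                  compute_se = FALSE))
  expect_true(fit$converged)
  est <- fit$estimates
  # with near-zero residual noise the estimator must hit the finite-sample
  # estimand: the truth corrected for the realized mean of the drawn etas
  # and for the dataset-median covariate normalisers
  med_crcl <- median(vapply(gen$study, function(p) p$covariates$crcl,
                            numeric(1)))
  med_alt <- median(vapply(gen$study, function(p) p$covariates$alt,
                           numeric(1)))
  expect_equal(unname(est["tvV"]),
               16.1 * exp(mean(gen$truth$eta[, 1])), tolerance = 0.02)
  expect_equal(unname(est["tvV2"]), 50.5 * (med_alt / 37)^0.635,
               tolerance = 0.02)
  expect_equal(unname(est["tvCL"]),
               1.50 * (med_crcl / 57.5)^0.353 *
                 exp(mean(gen$truth$eta[, 2])), tolerance = 0.02)
  expect_equal(unname(est["tvCL2"]), 1.71, tolerance = 0.02)
  # the CrCL exponent estimand carries the sampling covariance between the
  # drawn etas and log CrCL (a least-squares identity); V2 carries no eta
  lcrcl <- log(vapply(gen$study, function(p) p$covariates$crcl, numeric(1)))
  b_cl <- 0.353 + cov(lcrcl, gen$truth$eta[, 2]) / var(lcrcl)
  expect_equal(unname(est["dCLdCRCL"]), b_cl, tolerance = 0.05)
  expect_equal(unname(est["dV2dALT"]), 0.635, tolerance = 0.05)
})

test_that("AIC/BIC identities and likelihood-ratio nesting hold", {
  gen <- generate_study(recovery_design(25, seed = 13))
  base <- suppressWarnings(fit_ppk(base_model_spec(), gen$study,
                                   compute_se = FALSE))
  expect_equal(base$aic, base$neg2ll + 2 * base$n_params)
  expect_equal(base$bic, base$neg2ll + log(base$n_obs) * base$n_params)
  ext_spec <- model_spec(2, list(CL = list(crcl = "power")), c("V", "CL"))
  ext <- suppressWarnings(fit_ppk(ext_spec, gen$study,
    inits = c(as.list(base$estimates), list(dCLdCRCL = 0)),
    compute_se = FALSE))
  # adding a parameter never worsens the minimised -2LL
  expect_lte(ext$neg2ll, base$neg2ll + 1e-6)
  # stationarity: refitting from the solution leaves the objective unchanged
  refit <- suppressWarnings(fit_ppk(ext_spec, gen$study,
    inits = as.list(ext$estimates), compute_se = FALSE))
  expect_equal(refit$neg2ll, ext$neg2ll, tolerance = 1e-4)
})

test_that("fit reports CV%, shrinkage and convergence diagnostics", {
  gen <- generate_study(recovery_design(30, seed = 17))
  fit <- suppressWarnings(fit_ppk(final_model_spec(), gen$study))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$cv_percent)))
  expect_true(all(fit$cv_percent >= 0))
  # well-identified parameters carry informative uncertainty
  expect_true(all(fit$cv_percent[c("tvV", "tvCL", "sigma_prop")] > 0))
  expect_length(fit$eta_shrinkage, 2)
  expect_true(all(fit$eta_shrinkage < 100))
  expect_equal(fit$n_subjects, 30)
  # report round-trips through JSON
  f <- tempfile(fileext = ".json")
  write_fit_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$estimates$tvV, unname(fit$estimates["tvV"]))
})

test_that("SCM selects the true covariates and honors its thresholds", {
  des <- study_design(n_patients = 40,
    covariate_ranges = list(crcl = c(6.5, 193.8, 57.5),
                            alt = c(7, 495, 37),
                            weight = c(45, 65, 55), age = c(18, 92, 60.5)),
    regimen_fixed = regimen(0.75, 12, infusion_duration = 2),
    sample_times = c(59.95, 62, 62.5, 64, 67, 71.5),
    urine_subset_size = 0, horizon = 72, seed = 11)
  gen <- generate_study(des)
  cands <- list(list(param = "CL", cov = "crcl", form = "power"),
                list(param = "V2", cov = "alt", form = "power"),
                list(param = "CL", cov = "weight", form = "power"))
  res <- suppressWarnings(scm(base_model_spec(), gen$study, cands))
  expect_true("crcl" %in% names(res$final_assignments$CL))
  expect_true("alt" %in% names(res$final_assignments$V2))
  expect_false("weight" %in% names(res$final_assignments$CL))
  acc <- res$forward_trace[res$forward_trace$accepted, ]
  expect_true(all(acc$dofv > 3.84))
  # every retained covariate's removal raises the OFV by > 6.63
  kept <- res$backward_trace[!res$backward_trace$accepted, ]
  expect_true(all(kept$dofv > 6.63))
  # empty candidate list returns the base model unchanged
  res0 <- suppressWarnings(scm(base_model_spec(), gen$study, list()))
  expect_length(res0$final_assignments, 0)
  expect_equal(nrow(res0$forward_trace), 0)
})

test_that("bootstrap resamples subjects and summarises percentiles", {
  gen <- generate_study(recovery_design(15, seed = 23))
  fit <- suppressWarnings(fit_ppk(final_model_spec(), gen$study,
                                  compute_se = FALSE))
  bs <- suppressWarnings(bootstrap_ppk(fit, gen$study, n_resamples = 5,
                                       seed = 3))
  expect_true(all(bs$summary$ci_lower <= bs$summary$median + 1e-12))
  expect_true(all(bs$summary$median <= bs$summary$ci_upper + 1e-12))
  expect_equal(nrow(bs$draws) + bs$n_failed, 5)
  # the identity resample reproduces the point estimates (stationarity)
  refit <- suppressWarnings(fit_ppk(fit$spec, gen$study,
    inits = as.list(fit$estimates), compute_se = FALSE))
  expect_equal(refit$estimates, fit$estimates, tolerance = 1e-3)
})

test_that("pcVPC degenerates to the prediction when variability vanishes", {
  pop0 <- pop_params(omega2_V = 0, omega2_CL = 0, sigma_prop = 1e-12)
  des <- recovery_design(12, seed = 29)
  des$true_params <- pop0
  gen <- generate_study(des)
  # a fit object carrying the exact generating parameters
  spec <- final_model_spec()
  fit <- structure(list(
    estimates = c(tvV = 16.1, tvV2 = 50.5, tvCL = 1.5, tvCL2 = 1.71,
                  dCLdCRCL = 0.353, dV2dALT = 0.635, omega2_V = 0,
                  omega2_CL = 0, sigma_prop = 1e-12),
    spec = spec, refs = list(crcl = 57.5, alt = 37)), class = "ppk_fit")
  v <- pcvpc(fit, gen$study, n_sim = 100, seed = 1, n_bins = 4)
  expect_true(all(abs(v$bins$obs_p5 - v$bins$obs_p95) <
                    1e-6 * v$bins$obs_p50))
  expect_true(all(v$bins$p5_lo <= v$bins$p95_hi))
  # refs at the design medians: observed percentiles equal the simulated ones
  expect_equal(v$bins$obs_p50, (v$bins$p50_lo + v$bins$p50_hi) / 2,
               tolerance = 1e-6)
})

test_that("self-VPC: observed percentiles sit inside the simulated bands", {
  gen <- generate_study(recovery_design(40, seed = 37))
  fit <- structure(list(
    estimates = c(tvV = 16.1, tvV2 = 50.5, tvCL = 1.5, tvCL2 = 1.71,
                  dCLdCRCL = 0.353, dV2dALT = 0.635, omega2_V = 0.0267,
                  omega2_CL = 0.197, sigma_prop = 0.228),
    spec = final_model_spec(), refs = list(crcl = 57.5, alt = 37)),
    class = "ppk_fit")
  v <- suppressWarnings(pcvpc(fit, gen$study, n_sim = 200, seed = 2,
                              n_bins = 5))
  inside <- c(
    v$bins$obs_p5 >= v$bins$p5_lo & v$bins$obs_p5 <= v$bins$p5_hi,
    v$bins$obs_p50 >= v$bins$p50_lo & v$bins$obs_p50 <= v$bins$p50_hi,
    v$bins$obs_p95 >= v$bins$p95_lo & v$bins$obs_p95 <= v$bins$p95_hi)
  expect_gte(mean(inside), 0.7)
})
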