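test_that("individual_params reproduces the covariate equations", {
  pop <- pop_params()
  ref <- covariates(crcl = 57.5, alt = 37, weight = 55, age = 60)
  ind <- individual_params(pop, ref)
  expect_equal(ind$CL, 1.50)
  expect_equal(ind$V, 16.1)
  expect_equal(ind$V2, 50.5)
  expect_equal(ind$CL2, 1.71)
  # power function of CrCL on CL
  ind2 <- individual_params(pop, covariates(115, 37, 55, 60))
  expect_equal(ind2$CL, 1.50 * 2^0.353)
  # exponent-zero identity: covariates drop out
  pop0 <- pop_params(dV2dALT = 0, dCLdCrCL = 0)
  ind3 <- individual_params(pop0, covariates(150, 400, 55, 60))
  expect_equal(ind3$CL, 1.50)
  expect_equal(ind3$V2, 50.5)
  expect_error(individual_params(pop, list(crcl = -1, alt = 30)),
               "positive")
  # monotone in CrCL (CL) and ALT (V2) for positive exponents
  cl <- vapply(c(10, 50, 100, 190), function(x)
    individual_params(pop, covariates(x, 37, 55, 60))$CL, numeric(1))
  expect_true(all(diff(cl) > 0))
  v2 <- vapply(c(10, 50, 100, 400), function(x)
    individual_params(pop, covariates(57.5, x, 55, 60))$V2, numeric(1))
  expect_true(all(diff(v2) > 0))
})

test_that("closed-form profile matches the matrix-exponential oracle", {
  pop <- pop_params()
  ind <- individual_params(pop, covariates(57.5, 37, 55, 60))
  doses <- list(dose_event(0, 22, 2))
  times <- c(0, 0.5, 1, 2, 2.01, 3, 6, 12, 24, 48)
  got <- simulate_profile(ind, doses, times)$conc
  ora <- expm_conc(times, doses, ind$V, ind$V2, ind$CL, ind$CL2)
  expect_equal(got, ora, tolerance = 1e-6)
  # randomized parameter/dose property sweep
  set.seed(42)
  for (i in 1:25) {
    V <- runif(1, 5, 60); V2 <- runif(1, 10, 300)
    CL <- runif(1, 0.3, 8); CL2 <- runif(1, 0.3, 8)
    ind_r <- structure(list(V = V, V2 = V2, CL = CL, CL2 = CL2),
                       class = "individual_params")
    dl <- list(dose_event(0, runif(1, 10, 90), runif(1, 0.5, 3)),
               dose_event(runif(1, 6, 14), runif(1, 10, 90),
                          runif(1, 0.5, 3)))
    tt <- sort(runif(8, 0, 30))
    got <- simulate_profile(ind_r, dl, tt)$conc
    ora <- expm_conc(tt, dl, V, V2, CL, CL2)
    expect_equal(got, ora, tolerance = 1e-6)
    expect_true(all(got >= 0))
  }
})

test_that("superposition and the initial condition hold", {
  ind <- individual_params(pop_params(), covariates(57.5, 37, 55, 60))
  d1 <- list(dose_event(0, 22, 2))
  d2 <- list(dose_event(12, 33, 1))
  tt <- seq(0, 30, by = 1.5)
  both <- simulate_profile(ind, c(d1, d2), tt)$conc
  expect_equal(both, simulate_profile(ind, d1, tt)$conc +
                 simulate_profile(ind, d2, tt)$conc)
  expect_equal(simulate_profile(ind, d1, 0)$conc, 0)
})

test_that("with CL2 -> 0 the model collapses to the one-compartment form", {
  ind2 <- structure(list(V = 20, V2 = 50, CL = 2, CL2 = 1e-10),
                    class = "individual_params")
  ind1 <- structure(list(V = 20, V2 = 1, CL = 2, CL2 = 0),
                    class = "individual_params")
  doses <- list(dose_event(0, 44, 2))
  tt <- c(0.5, 1, 2, 4, 8, 16, 30)
  expect_equal(simulate_profile(ind2, doses, tt)$conc,
               simulate_profile(ind1, doses, tt, ncmt = 1)$conc,
               tolerance = 1e-6)
})

test_that("repeated macro-root parameters route to the analytic limit", {
  # alpha == beta needs k12 -> 0 with k10 == k21; pick CL2 small enough
  # that the macro-root gap falls below the degeneracy tolerance:
  # k10 = k21 = 0.1, k12 ~ 2.5e-21
  ind_deg <- structure(list(V = 10, V2 = 2.5e-19, CL = 1, CL2 = 2.5e-20),
                       class = "individual_params")
  ind_1cmt <- structure(list(V = 10, V2 = 1, CL = 1, CL2 = 0),
                        class = "individual_params")
  doses <- list(dose_event(0, 50, 1))
  tt <- c(0.5, 1, 2, 5, 10, 20)
  got <- simulate_profile(ind_deg, doses, tt)$conc
  # in this limit the kinetics are monoexponential with k = 0.1
  ora <- simulate_profile(ind_1cmt, doses, tt, ncmt = 1)$conc
  expect_equal(got, ora, tolerance = 1e-8)
  expect_true(all(is.finite(got)))
})

test_that("analytic AUC: dose/CL identity, quadrature agreement, errors", {
  ind <- individual_params(pop_params(), covariates(57.5, 37, 55, 60))
  doses <- list(dose_event(0, 22, 2))
  expect_equal(model_auc(ind, doses, 0, Inf), 22 / ind$CL)
  set.seed(7)
  for (i in 1:5) {
    ind_r <- structure(list(V = runif(1, 5, 40), V2 = runif(1, 20, 200),
                            CL = runif(1, 0.5, 5), CL2 = runif(1, 0.5, 5)),
                       class = "individual_params")
    D <- runif(1, 20, 80)
    expect_equal(model_auc(ind_r, list(dose_event(0, D, 1.5)), 0, Inf),
                 D / ind_r$CL, tolerance = 1e-12)
  }
  # quadrature oracle on a dense grid
  dl <- list(dose_event(0, 33, 2), dose_event(12, 33, 2))
  tt <- seq(0, 36, by = 0.01)
  cc <- simulate_profile(ind, dl, tt)$conc
  expect_equal(model_auc(ind, dl, 0, 36), trapz(tt, cc), tolerance = 1e-3)
  expect_equal(model_auc(ind, dl, 10, 25),
               trapz(tt[tt >= 10 & tt <= 25], cc[tt >= 10 & tt <= 25]),
               tolerance = 1e-3)
  expect_error(model_auc(ind, dl, 10, 5), "t1 > t0")
})

test_that("exposure metrics: steady-state identities and linearity", {
  # CL = 1.50 L/h, 36 mg q12h at true steady state: css_avg = 2.0
  ind <- structure(list(V = 16.1, V2 = 50.5, CL = 1.50, CL2 = 1.71),
                   class = "individual_params")
  reg <- regimen(36 / 44, 12, infusion_duration = 2)  # 36 mg per dose
  m <- exposure_metrics(ind, reg, eval_day = 3)
  expect_equal(m$css_avg_inf, 36 / (1.50 * 12))
  # at a long horizon the interval average approaches the infinite-time value
  m200 <- exposure_metrics(ind, reg, eval_day = 100)
  expect_equal(m200$css_avg, m$css_avg_inf, tolerance = 1e-3)
  expect_true(m$css_min <= m$css_avg && m$css_avg <= m$css_max)
  # doubling all doses doubles every metric
  reg2 <- regimen(2 * 36 / 44, 12, infusion_duration = 2)
  m2 <- exposure_metrics(ind, reg2, eval_day = 3)
  for (f in c("auc_0_24_day1", "auc_24_day3", "css_min", "css_max",
              "css_avg"))
    expect_equal(m2[[f]], 2 * m[[f]], tolerance = 1e-10)
  # accumulation monotonicity: day-3 average below the infinite-time value
  expect_lt(m$css_avg, m$css_avg_inf)
})

test_that("profiles and parameter sets round-trip through CSV/JSON", {
  ind <- individual_params(pop_params(), covariates(57.5, 37, 55, 60))
  pr <- simulate_profile(ind, list(dose_event(0, 33, 2)), c(1, 2, 4))
  f <- tempfile(fileext = ".csv")
  write_profiles(list(a = pr), f)
  back <- read.csv(f)
  expect_equal(names(back), c("ID", "TIME", "CONC"))
  expect_equal(back$CONC, pr$conc)
  pj <- tempfile(fileext = ".json")
  write_pop_params(pop_params(tvCL = 1.8), pj)
  pop2 <- read_pop_params(pj)
  expect_s3_class(pop2, "pop_params")
  expect_equal(pop2$tvCL, 1.8)
  expect_equal(pop2$omega2_CL, 0.197)
})

test_that("proportional residual error has the stated first two moments", {
  expect_equal(add_residual_error(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(99)
  n <- 1e5
  y <- add_residual_error(rep(2, n), 0.2)
  se_mean <- 2 * 0.2 / sqrt(n)
  expect_lt(abs(mean(y) - 2), 3 * se_mean)
  expect_equal(var(y), (2 * 0.2)^2, tolerance = 0.05)
  # negative draws are truncated with a warning
  set.seed(1)
  expect_warning(add_residual_error(rep(0.5, 2000), 1.5), "truncated")
})
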