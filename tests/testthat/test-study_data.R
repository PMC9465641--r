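test_that("mu_to_mg applies the 44 mg/MU label conversion and is linear", {
  expect_equal(mu_to_mg(0.5), 22)
  expect_equal(mu_to_mg(1.5), 66)
  expect_equal(mu_to_mg(0), 0)
  expect_error(mu_to_mg(-1), "non-negative")
  set.seed(1)
  a <- runif(20, 0, 3); b <- runif(20, 0, 3)
  expect_equal(mu_to_mg(a + b), mu_to_mg(a) + mu_to_mg(b))
})

test_that("cockcroft_gault matches direct arithmetic and its monotonicities", {
  expect_equal(cockcroft_gault(60, 55, 1.0, "male"), 80 * 55 / 72,
               tolerance = 1e-12)
  expect_equal(cockcroft_gault(60, 55, 1.0, "male"), 61.11, tolerance = 1e-4)
  expect_equal(cockcroft_gault(60, 55, 1.0, "female"), 51.94,
               tolerance = 1e-3)
  expect_equal(cockcroft_gault(139, 55, 1.0, "male"), 55 / 72,
               tolerance = 1e-12)
  expect_error(cockcroft_gault(60, 55, 0, "male"), "creatinine")
  # female = 0.85 x male at identical inputs; strict monotonicities
  set.seed(2)
  for (i in 1:20) {
    age <- runif(1, 20, 100); wt <- runif(1, 40, 90)
    scr <- runif(1, 0.4, 5)
    m <- cockcroft_gault(age, wt, scr, "male")
    expect_equal(cockcroft_gault(age, wt, scr, "female"), 0.85 * m)
    expect_lt(cockcroft_gault(age + 5, wt, scr, "male"), m)
    expect_lt(cockcroft_gault(age, wt, scr * 1.2, "male"), m)
    expect_gt(cockcroft_gault(age, wt + 5, scr, "male"), m)
  }
})

test_that("total colistin sums the two components, incl. the LLOQ bound", {
  expect_equal(total_colistin(0.5, 0.7), 1.2)
  expect_equal(total_colistin(0, 0), 0)
  expect_equal(total_colistin(0.034, 0.059), 0.093)
  expect_equal(assay_config()$lloq_total, 0.093)
  expect_error(total_colistin(-0.1, 0.5), "non-negative")
})

test_that("domain constructors enforce their invariants", {
  expect_error(dose_event(-1, 22, 2))
  expect_error(dose_event(0, 0, 2))
  expect_error(dose_event(0, 22, 0))
  expect_error(urine_interval(5, 5, 1, 1))
  expect_error(covariates(crcl = 0, alt = 30, weight = 55, age = 60))
  expect_error(covariates(crcl = 60, alt = 30, weight = 55, age = 17))
  expect_error(regimen(0.5, 6))
  expect_error(patient_record(1, covariates(60, 30, 55, 60), doses = list()))
  # plasma times must be non-decreasing
  expect_error(patient_record(1, covariates(60, 30, 55, 60),
    doses = list(dose_event(0, 22, 2)),
    plasma = list(plasma_sample(5, 1), plasma_sample(3, 1))),
    "non-decreasing")
  # BLQ flag is set from the total-drug assay limit
  expect_true(plasma_sample(1, 0.05, "random")$below_lloq)
  expect_false(plasma_sample(1, 0.093, "random")$below_lloq)
})

test_that("regimen_doses expands loading + maintenance schedules", {
  reg <- regimen(0.5, 12, loading_dose = 1.0, infusion_duration = 2)
  doses <- regimen_doses(reg, horizon = 48)
  expect_equal(length(doses), 4)  # load at 0, maintenance at 12/24/36
  expect_equal(doses[[1]]$amount, 44)
  expect_equal(doses[[2]]$amount, 22)
  expect_equal(vapply(doses, `[[`, numeric(1), "start_time"),
               c(0, 12, 24, 36))
  expect_equal(daily_dose_mg(regimen(0.5, 8)), 66)
})

test_that("event dataset round-trips through CSV with full precision", {
  study <- tiny_study()
  f <- tempfile(fileext = ".csv")
  write_dataset(study, f)
  back <- read_dataset(f)
  expect_length(back, 2)
  expect_equal(length(back[[1]]$doses), 2)
  expect_equal(length(back[[1]]$plasma), 3)
  expect_equal(back[[2]]$covariates$sex, "female")
  expect_equal(back[[2]]$covariates$extras$alb, 28)
  for (i in 1:2) {
    expect_equal(vapply(back[[i]]$plasma, `[[`, numeric(1), "concentration"),
                 vapply(study[[i]]$plasma, `[[`, numeric(1), "concentration"))
    expect_equal(vapply(back[[i]]$doses, `[[`, numeric(1),
                        "infusion_duration"),
                 vapply(study[[i]]$doses, `[[`, numeric(1),
                        "infusion_duration"))
  }
  # write(read(f)) is byte-identical to write(f)
  f2 <- tempfile(fileext = ".csv")
  write_dataset(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("dialect violations are reported with line numbers", {
  study <- tiny_study()
  f <- tempfile(fileext = ".csv")
  write_dataset(study, f)
  df <- read.csv(f)
  # DV on a dosing row
  bad <- df
  bad$DV[bad$EVID == 1][1] <- 1.5
  fb <- tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE, na = "")
  expect_error(read_dataset(fb), "EVID=1.*line")
  # observation before first dose
  bad2 <- df
  i <- which(bad2$EVID == 0)[1]
  bad2$TIME[i] <- -1
  # keep within-patient order irrelevant; reader sorts by time
  write.csv(bad2, fb, row.names = FALSE, na = "")
  expect_error(read_dataset(fb), "before first dose")
  # missing mandatory covariate column
  bad3 <- df[, setdiff(names(df), "ALT")]
  write.csv(bad3, fb, row.names = FALSE, na = "")
  expect_error(read_dataset(fb), "ALT")
})

test_that("urine CSV round-trips and attaches to the right patients", {
  study <- tiny_study()
  f <- tempfile(fileext = ".csv")
  write_urine(study, f)
  by_id <- read_urine(f)
  expect_named(by_id, "2")
  expect_length(by_id[["2"]], 2)
  stripped <- study
  stripped[[2]]$urine <- list()
  back <- read_urine(f, stripped)
  expect_length(back[[2]]$urine, 2)
  expect_equal(back[[2]]$urine[[1]]$volume, 0.8)
})
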