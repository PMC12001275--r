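test_that("degenerate generator reproduces the closed-form steady state", {
  cfg <- cohort_config_5fu(n_patients = 6, omega = 0, error_b = 0,
                           bsa_slope = 0)
  coh <- generate_5fu_cohort(cfg, seed = 3)
  ev <- coh$dataset$events
  obs <- ev[ev$EVT == "obs", ]
  dose <- ev[ev$EVT == "dose", ]
  expected <- css_5fu(dose$AMT[match(obs$ID, dose$ID)], 24, 223)
  expect_equal(obs$DV, expected, tolerance = 1e-8)
  # noise-free truth equals the event-table values when b = 0
  expect_equal(coh$truth$observations$conc_true, obs$DV,
               tolerance = 1e-12)
})

test_that("noise-free generator output comes from the structural solver", {
  cfg <- cohort_config_5fu(n_patients = 3, error_b = 0)
  coh <- generate_5fu_cohort(cfg, seed = 5)
  spec <- structural_model("fu5")
  for (i in 1:3) {
    p <- coh$truth$patients[i, ]
    o <- coh$truth$observations[
      coh$truth$observations$patient_id == p$patient_id, ]
    reg <- data.frame(time = 0, amount = p$dose * 26 / 24, duration = 26,
                      route = "iv_infusion")
    redo <- solve_profile(spec, c(CL = p$cl_true, V = 46.1), reg, o$time)
    expect_equal(o$conc_true, unname(redo[, "parent"]), tolerance = 1e-10)
  }
})

test_that("clearance variability and covariate effects match construction", {
  cfg <- cohort_config_5fu(n_patients = 5000, bsa_slope = 0,
                           concentrations = FALSE)
  coh <- generate_5fu_cohort(cfg, seed = 77)
  # omega = 0.3 recovered by the law of large numbers at n = 5000
  expect_true(abs(stats::sd(log(coh$truth$patients$cl_true)) - 0.3) < 0.01)
  expect_equal(stats::sd(coh$truth$patients$eta), 0.3, tolerance = 0.02)
  # positive BSA slope induces a positive log CL ~ BSA regression slope
  cfg2 <- cohort_config_5fu(n_patients = 800, concentrations = FALSE)
  coh2 <- generate_5fu_cohort(cfg2, seed = 78)
  sl <- stats::coef(stats::lm(log(cl_true) ~ bsa,
                              data = coh2$truth$patients))[2]
  expect_gt(sl, 0.2)
  # demographics near the emulated study: BSA median and dose median
  expect_equal(stats::median(coh$truth$patients$bsa), 1.915,
               tolerance = 0.05)
  expect_true(abs(stats::median(coh$truth$patients$dose) - 4000) < 300)
})

test_that("oral-design generator injects missingness at the stated rates", {
  cfg <- cohort_config_sunitinib(n_patients = 5000,
                                 concentrations = FALSE)
  coh <- generate_sunitinib_cohort(cfg, seed = 15)
  tp <- coh$truth$patients
  expect_lt(abs(mean(tp$weight_missing) - 0.129), 0.02)
  expect_lt(abs(mean(tp$height_missing) - 0.109), 0.02)
  expect_lt(abs(mean(tp$bsa_missing) - 0.066), 0.02)
  # masks land in the event table as NA, never sentinel values
  ev <- coh$dataset$events
  miss_ids <- tp$patient_id[tp$weight_missing]
  expect_true(all(is.na(ev$WT[ev$ID %in% miss_ids])))
  expect_false(any(ev$WT %in% c(0, -99), na.rm = TRUE))
})

test_that("trough samples precede that day's intake and IIV scales profiles", {
  cfg <- cohort_config_sunitinib(n_patients = 12, concentrations = FALSE)
  coh <- generate_sunitinib_cohort(cfg, seed = 21)
  ev <- coh$dataset$events
  obs <- ev[ev$EVT == "obs", ]
  doses <- ev[ev$EVT == "dose", ]
  for (r in seq_len(nrow(obs))) {
    same_day_dose <- doses$TIME[doses$ID == obs$ID[r] &
                                  doses$TIME > obs$TIME[r] &
                                  doses$TIME - obs$TIME[r] <= 24]
    if (length(same_day_dose) > 0)
      expect_true(all(obs$TIME[r] < same_day_dose))
  }
  # schedule: no dose events during the off weeks
  day <- doses$TIME / 24
  expect_true(all((day %% 42) < 28))
  # zero IIV and zero noise: two equal-weight patients share a profile
  pop <- default_popset("sunitinib")
  th1 <- allometric_scale(individual_params(
    pop, stats::setNames(rep(0, 4), pop$iiv)), 80)
  th2 <- allometric_scale(individual_params(
    pop, stats::setNames(rep(0, 4), pop$iiv)), 80)
  expect_identical(th1, th2)
})

test_that("preprocessing fixtures reproduce the published bookkeeping", {
  fx <- generate_acceptance_fixture_5fu()
  ev <- fx$events
  expect_equal(length(unique(ev$ID)), 157L)
  expect_equal(sum(ev$EVT == "obs"), 549L)
  res <- apply_exclusions_5fu(fx)
  expect_equal(res$report$n_excluded, 8L)
  expect_equal(length(res$report$excluded_patient_ids), 8L)
  # exactly one excluded patient loses their only sample
  expect_equal(res$report$n_patients_kept, 156L)

  sx <- generate_acceptance_fixture_sunitinib()
  expect_equal(length(unique(sx$events$ID)), 47L)
  flt <- apply_exclusions_sunitinib(sx)
  expect_equal(flt$report$n_excluded_parent, 6L)
  expect_equal(length(flt$report$excluded_patient_ids), 5L)
  expect_equal(flt$report$n_patients_kept, 47L)
})

test_that("fixtures regenerate byte-identically", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(generate_acceptance_fixture_5fu(), p1)
  write_pk_dataset(generate_acceptance_fixture_5fu(), p2)
  expect_identical(readLines(p1), readLines(p2))
  write_pk_dataset(generate_acceptance_fixture_sunitinib(), p1)
  write_pk_dataset(generate_acceptance_fixture_sunitinib(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generators restore the caller's RNG state", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_5fu_cohort(cohort_config_5fu(n_patients = 2,
                                                  concentrations = FALSE),
                                seed = 9))
  expect_identical(.Random.seed, before)
})
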