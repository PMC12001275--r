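test_that("event-record files parse into datasets and round-trip exactly", {
  ev <- toy_fu5_events("P1", 4000, list(c(18.5, 21)), list(c(0.7, 0.81)))
  ev$WT[2] <- NA  # missing covariate carried as mask
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(pk_dataset(ev, "fu5"), path)

  ds <- read_pk_dataset(path, "fu5")
  expect_s3_class(ds, "pk_dataset")
  pats <- pk_patients(ds)
  expect_length(pats, 1L)
  expect_equal(nrow(pats$P1$doses), 1L)
  expect_equal(nrow(pats$P1$observations), 2L)
  expect_equal(pats$P1$doses$amount, 4000)
  expect_equal(pats$P1$doses$duration, 24)
  expect_equal(pats$P1$doses$route, "iv_infusion")

  # full-precision round trip including the missing mask
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, path2)
  ds2 <- read_pk_dataset(path2, "fu5")
  expect_equal(ds2$events, ds$events, tolerance = 0)
  expect_identical(is.na(ds2$events$WT), is.na(ds$events$WT))
})

test_that("schema and parse errors name the offending column and row", {
  ev <- toy_fu5_events("P1", 4000, list(20), list(0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(pk_dataset(ev, "fu5"), path)

  txt <- readLines(path)
  writeLines(sub("^ID", "PATIENT", txt), path)
  expect_error(read_pk_dataset(path, "fu5"), "ID")

  ev_bad <- ev
  ev_bad$DV[ev_bad$EVT == "obs"] <- 0.75  # exactly representable
  write_pk_dataset(pk_dataset(ev_bad, "fu5"), path)
  txt <- readLines(path)
  txt[3] <- sub("0.75", "abc", txt[3], fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_pk_dataset(path, "fu5"), "abc")

  expect_error(pk_dataset(ev[, -1], "fu5"), "ID")
})

test_that("implied-clearance rule keeps plausible and drops implausible samples", {
  # CL = D/(IT*C): 4000/(24*0.70) = 238.1 kept; 4000/(24*0.10) = 1666.7 dropped
  ev <- toy_fu5_events(c("A", "B"), c(4000, 4000),
                       list(c(18, 20), 19), list(c(0.70, 0.10), 0.75))
  res <- apply_exclusions_5fu(pk_dataset(ev, "fu5"))
  expect_equal(res$report$n_obs_raw, 3L)
  expect_equal(res$report$n_obs_kept, 2L)
  expect_equal(unname(res$report$n_excluded_by_reason["implied_clearance"]),
               1L)
  kept <- res$dataset$events
  expect_false(any(kept$EVT == "obs" & kept$DV == 0.10))
})

test_that("patients with no remaining samples are removed entirely", {
  ev <- toy_fu5_events(c("A", "B"), c(4000, 4000),
                       list(20, 21), list(0.04, 0.8))  # A is all-BLQ
  res <- apply_exclusions_5fu(pk_dataset(ev, "fu5"))
  expect_equal(res$report$n_patients_raw, 2L)
  expect_equal(res$report$n_patients_kept, 1L)
  expect_false("A" %in% res$dataset$events$ID)
})

test_that("exclusion filters are idempotent and counts are conserved", {
  fx <- generate_acceptance_fixture_5fu()
  r1 <- apply_exclusions_5fu(fx)
  r2 <- apply_exclusions_5fu(r1$dataset)
  expect_equal(r2$report$n_excluded, 0L)
  expect_identical(r2$dataset$events, r1$dataset$events)
  expect_equal(r1$report$n_obs_kept + r1$report$n_excluded,
               r1$report$n_obs_raw)

  sx <- generate_acceptance_fixture_sunitinib()
  s1 <- apply_exclusions_sunitinib(sx)
  s2 <- apply_exclusions_sunitinib(s1$dataset)
  expect_equal(s2$report$n_excluded_parent, 0L)
  expect_equal(s1$report$n_parent_kept + s1$report$n_excluded_parent,
               s1$report$n_parent_raw)
  expect_equal(s1$report$n_metab_kept + s1$report$n_excluded_metab,
               s1$report$n_metab_raw)
})

test_that("BLQ parent samples drag their paired metabolite sample along", {
  base <- toy_fu5_events("S1", 50, list(c(100, 200)), list(c(30, 0.05)),
                         dur = 0)
  base$DUR[base$EVT == "dose"] <- 0
  met <- base[base$EVT == "obs", ]
  met$ANALYTE <- "metab"
  met$DV <- c(10, 12)
  ev <- rbind(base, met)
  ds <- pk_dataset(ev, "sunitinib")
  res <- apply_exclusions_sunitinib(ds)
  expect_equal(res$report$n_excluded_parent, 1L)
  expect_equal(res$report$n_excluded_metab, 1L)
  expect_equal(res$report$n_parent_kept, res$report$n_metab_kept)
  # the paired metabolite value 12 at t=200 went with the 0.05 parent
  expect_false(any(res$dataset$events$DV == 12, na.rm = TRUE))
  # above-threshold parent (0.07) is kept
  ev2 <- ev
  ev2$DV[ev2$DV == 0.05] <- 0.07
  res2 <- apply_exclusions_sunitinib(pk_dataset(ev2, "sunitinib"))
  expect_equal(res2$report$n_excluded_parent, 0L)
})

test_that("cross-validation splits are patient-level partitions", {
  ids <- sprintf("P%02d", 1:10)
  splits <- split_cv(ids, n_repeats = 3, n_folds = 5, seed = 11)
  expect_length(splits, 15L)
  for (r in 1:3) {
    rep_splits <- Filter(function(s) s$repeat_index == r, splits)
    test_sets <- lapply(rep_splits, `[[`, "test_patient_ids")
    expect_equal(lengths(test_sets), rep(2L, 5L))
    expect_setequal(unlist(test_sets), ids)      # partition
    for (s in rep_splits) {
      expect_length(intersect(s$train_patient_ids, s$test_patient_ids), 0L)
      expect_setequal(c(s$train_patient_ids, s$test_patient_ids), ids)
    }
  }
  # each patient tested exactly n_repeats times over all repeats
  all_test <- unlist(lapply(splits, `[[`, "test_patient_ids"))
  expect_true(all(table(all_test) == 3L))
  # determinism
  expect_identical(splits, split_cv(ids, 3, 5, seed = 11))
  expect_error(split_cv(ids[1:3], 1, 5, seed = 1), "at least")
})

test_that("weight imputation uses training-set means by sex, never the target", {
  tr_ev <- toy_fu5_events(c("M1", "M2", "F1"), c(4000, 4000, 4000),
                          list(20, 20, 20), list(0.7, 0.7, 0.7),
                          wt = c(70, 90, 60), sex = c(1, 1, 0))
  tg_ev <- toy_fu5_events(c("T1", "T2"), c(4000, 4000),
                          list(20, 20), list(0.7, 0.7),
                          wt = c(NA, 100), sex = c(1, 1))
  train <- pk_dataset(tr_ev, "fu5")
  target <- pk_dataset(tg_ev, "fu5")
  out <- impute_weight_by_sex(train, target)
  p <- pk_patients(out)
  expect_equal(unname(p$T1$covariates["WT"]), 80)  # (70+90)/2, not using 100
  expect_equal(unname(p$T2$covariates["WT"]), 100) # unchanged
  # no missing weights -> identity
  out2 <- impute_weight_by_sex(train, train)
  expect_identical(out2$events, train$events)
  # a sex with no observed training weights errors
  tr2 <- tr_ev; tr2$WT <- ifelse(tr2$SEX == 1, NA, tr2$WT)
  expect_error(impute_weight_by_sex(pk_dataset(tr2, "fu5"), target), "sex")
})
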