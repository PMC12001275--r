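# Virtual-cohort generators with known ground truth, emulating the two
# study designs: (a) steady-state 24 h fluorouracil infusions with
# BSA-dependent clearance, log-normal IIV and proportional error;
# (b) daily oral sunitinib on a 4-week-on/2-week-off schedule with trough
# sampling, paired parent/metabolite observations, allometric scaling and
# covariate missingness. Deterministic fixtures reproduce the published
# preprocessing bookkeeping of both designs (these are synthetic
# stand-ins; the real cohorts are not public).

.du_bois_weight <- function(bsa, height) {
  (bsa / (0.007184 * height^0.725))^(1 / 0.425)
}

# James formula; weight kg, height cm
.james_lbm <- function(weight, height, sex) {
  ifelse(sex == 1,
         1.10 * weight - 128 * (weight / height)^2,
         1.07 * weight - 148 * (weight / height)^2)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- (x < lo | x > hi)))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# multiplicative proportional noise, redrawn on the rare nonpositive draw
.prop_noise <- function(y, b) {
  f <- 1 + b * stats::rnorm(length(y))
  while (any(bad <- (f <= 0)))
    f[bad] <- 1 + b * stats::rnorm(sum(bad))
  y * f
}

#' Configuration of the fluorouracil virtual cohort
#'
#' Defaults emulate the study design: 157 patients, weekly 24 h infusions
#' dosed per body surface area (about 2100 mg/m^2, clipped to the
#' observed 2700-5720 mg range, median near 4000 mg), steady-state
#' sampling 16.8-25.0 h after infusion start, 1-9 samples per patient
#' (median 3), typical clearance 223 L/h with a linear BSA effect
#' centered on the population median BSA of 1.915 m^2, log-normal IIV
#' (omega = 0.3) and proportional residual error (b = 0.2).
#'
#' The BSA slope defaults to `tv_cl / bsa_ref` (about 116 L/h per m^2),
#' the linearization of a clearance proportional to BSA.
#'
#' @param n_patients cohort size.
#' @param tv_cl typical clearance (L/h).
#' @param v volume of distribution (L).
#' @param omega SD of the log-normal clearance IIV.
#' @param bsa_slope linear BSA effect on clearance (L/h per m^2).
#' @param bsa_ref centering value for the BSA effect (m^2).
#' @param error_b proportional residual error coefficient.
#' @param dose_per_m2 nominal dose rate (mg/m^2), clipped to `dose_range`.
#' @param dose_range administered dose limits (mg).
#' @param infusion_duration nominal infusion duration (h).
#' @param sampling_window steady-state sampling window (h after infusion
#'   start).
#' @param samples_prob probabilities of 1..9 samples per patient.
#' @param concentrations if `FALSE`, generate covariates, doses, sampling
#'   times and ground-truth parameters only (no solver calls) — useful
#'   for demographic/parameter checks at large n.
#' @return A list of class `cohort_config_5fu`.
#' @export
cohort_config_5fu <- function(n_patients = 157, tv_cl = 223, v = 46.1,
                              omega = 0.3,
                              bsa_slope = tv_cl / bsa_ref,
                              bsa_ref = 1.915, error_b = 0.2,
                              dose_per_m2 = 2100,
                              dose_range = c(2700, 5720),
                              infusion_duration = 24,
                              sampling_window = c(16.8, 25.0),
                              samples_prob = c(0.15, 0.20, 0.22, 0.13,
                                               0.10, 0.08, 0.05, 0.04,
                                               0.03),
                              concentrations = TRUE) {
  stopifnot(n_patients >= 1, tv_cl > 0, v > 0, omega >= 0, error_b >= 0,
            infusion_duration > 0, length(samples_prob) == 9)
  structure(as.list(environment()), class = "cohort_config_5fu")
}

#' Generate a fluorouracil-like virtual cohort
#'
#' Covariates are drawn to match the study demographics (male fraction
#' 96/156; age median 64.5, range 35-83; BSA median near 1.915 on
#' 1.35-2.85 m^2; weight and height consistent with BSA through the
#' Du Bois relation; lean body mass by the James formula, fat mass as the
#' remainder). True clearance is
#' `CL_i = (tv_cl + bsa_slope * (BSA_i - bsa_ref)) * exp(eta_i)`,
#' `eta_i ~ N(0, omega^2)`. Noise-free concentrations come from the
#' structural solver with the infusion continuing at its nominal rate
#' through the sampling window (the samples are at steady state);
#' proportional noise multiplies them. The event table records the
#' nominal dose and 24 h duration.
#'
#' @param config a [cohort_config_5fu()].
#' @param seed integer seed.
#' @return List with `dataset` (a [pk_dataset()]) and `truth` (per-patient
#'   `eta`, true clearance and covariates; per-observation noise-free
#'   concentrations).
#' @export
generate_5fu_cohort <- function(config = cohort_config_5fu(), seed) {
  stopifnot(inherits(config, "cohort_config_5fu"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- config$n_patients
  sex <- stats::rbinom(n, 1L, 96 / 156)
  bsa <- .rtrunc_norm(n, 1.915, 0.25, 1.35, 2.85)
  age <- .rtrunc_norm(n, 64, 11, 35, 83)
  height <- ifelse(sex == 1, .rtrunc_norm(n, 176, 7, 150, 205),
                   .rtrunc_norm(n, 163, 7, 145, 195))
  weight <- .du_bois_weight(bsa, height)
  lbm <- .james_lbm(weight, height, sex)
  fm <- weight - lbm
  dose <- pmin(pmax(round(config$dose_per_m2 * bsa / 10) * 10,
                    config$dose_range[1L]), config$dose_range[2L])
  eta <- stats::rnorm(n, 0, config$omega)
  cl_true <- (config$tv_cl +
                config$bsa_slope * (bsa - config$bsa_ref)) * exp(eta)
  if (any(cl_true <= 0))
    stop("BSA effect drove a clearance nonpositive; reduce bsa_slope",
         call. = FALSE)
  n_samp <- sample(1:9, n, replace = TRUE, prob = config$samples_prob)
  it <- config$infusion_duration
  spec <- structural_model("fu5")
  horizon <- config$sampling_window[2L] + 1
  ev <- list(); tru_obs <- list()
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    times <- sort(stats::runif(n_samp[i], config$sampling_window[1L],
                               config$sampling_window[2L]))
    # infusion continuing at the nominal rate D/IT through the window
    if (config$concentrations) {
      regimen <- data.frame(time = 0, amount = dose[i] * horizon / it,
                            duration = horizon, route = "iv_infusion")
      conc <- solve_profile(spec, c(CL = cl_true[i], V = config$v),
                            regimen, times)[, "parent"]
      y <- .prop_noise(conc, config$error_b)
    } else {
      conc <- y <- rep(NA_real_, n_samp[i])
    }
    base <- data.frame(ID = ids[i], SEX = sex[i], AGE = age[i],
                       WT = weight[i], HT = height[i], BSA = bsa[i],
                       LBM = lbm[i], FM = fm[i],
                       stringsAsFactors = FALSE)
    ev[[length(ev) + 1L]] <- cbind(
      data.frame(TIME = c(0, times),
                 EVT = c("dose", rep("obs", n_samp[i])),
                 AMT = c(dose[i], rep(NA, n_samp[i])),
                 DUR = c(it, rep(NA, n_samp[i])),
                 DV = c(NA, y), ANALYTE = c("", rep("parent", n_samp[i])),
                 BLQ = c(NA, as.numeric(y < 0.052))),
      base[rep(1L, n_samp[i] + 1L), ])
    tru_obs[[length(tru_obs) + 1L]] <-
      data.frame(patient_id = ids[i], time = times, conc_true = conc)
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  ds <- pk_dataset(events, drug_type = "fu5",
                   provenance = "synthetic fluorouracil cohort")
  truth <- list(
    patients = data.frame(patient_id = ids, eta = eta, cl_true = cl_true,
                          bsa = bsa, sex = sex, weight = weight,
                          dose = dose),
    observations = do.call(rbind, tru_obs),
    config = config)
  list(dataset = ds, truth = truth)
}

#' Configuration of the sunitinib virtual cohort
#'
#' Defaults emulate the pooled oral-design studies: 47 patients, 37.5 or
#' 50 mg daily on a 4-week-on/2-week-off schedule, trough samples (30 min
#' before intake) over at most `n_cycles` 6-week cycles, 1-14 samples per
#' patient, paired parent/metabolite observations, covariate missingness
#' of 12.9% (weight), 10.9% (height), 6.6% (BSA), and a 0.06 ng/mL
#' quantification limit. Typical values default to [default_popset()];
#' IIV standard deviations apply to CLS, V2S, FM and V2M. The source
#' demographics for this arm are not published in full, so the covariate
#' distributions are documented implementer defaults.
#'
#' @param n_patients cohort size.
#' @param popset a [pop_parameters()] set supplying typical values.
#' @param omega named SDs of the log-normal IIV for the four IIV
#'   parameters.
#' @param error_b_parent,error_b_metab proportional error coefficients.
#' @param doses daily dose options (mg) with `dose_prob` probabilities.
#' @param dose_prob sampling probabilities of `doses`.
#' @param n_cycles number of 6-week cycles covered by sampling.
#' @param days_on,days_off treatment schedule within a cycle (days).
#' @param samples_prob probabilities of 1..14 samples per patient.
#' @param missing_weight,missing_height,missing_bsa covariate missingness
#'   rates.
#' @param blq_threshold quantification limit (ng/mL).
#' @param concentrations if `FALSE`, generate covariates, regimens and
#'   sampling times only (no ODE solves) — useful for demographic checks
#'   at large n.
#' @return A list of class `cohort_config_sunitinib`.
#' @export
cohort_config_sunitinib <- function(n_patients = 47,
                                    popset = default_popset("sunitinib"),
                                    omega = c(CLS = 0.40, V2S = 0.40,
                                              FM = 0.30, V2M = 0.40),
                                    error_b_parent = 0.25,
                                    error_b_metab = 0.25,
                                    doses = c(37.5, 50),
                                    dose_prob = c(0.7, 0.3),
                                    n_cycles = 2, days_on = 28,
                                    days_off = 14,
                                    samples_prob = c(2, 3, 4, 6, 8, 9, 9,
                                                     8, 6, 4, 3, 2, 1.5,
                                                     1) / 66.5,
                                    missing_weight = 0.129,
                                    missing_height = 0.109,
                                    missing_bsa = 0.066,
                                    blq_threshold = 0.06,
                                    concentrations = TRUE) {
  stopifnot(n_patients >= 1, length(samples_prob) == 14,
            all(c(missing_weight, missing_height, missing_bsa) >= 0),
            all(c(missing_weight, missing_height, missing_bsa) <= 1),
            days_on + days_off == 42)
  structure(as.list(environment()), class = "cohort_config_sunitinib")
}

#' Generate a sunitinib-like virtual cohort
#'
#' Per-patient parameters are built from the typical values with
#' log-normal IIV on CLS, V2S, FM and V2M, then allometrically scaled by
#' the patient's (latent, always-known-to-the-generator) weight. The
#' daily-dose regimen is realized as oral bolus events; noise-free
#' parent/metabolite profiles come from the structural solver at the
#' trough sampling times (30 min before that day's intake); proportional
#' noise is applied per analyte; covariate missingness masks and BLQ
#' flags are injected at the configured rates.
#'
#' @param config a [cohort_config_sunitinib()].
#' @param seed integer seed.
#' @return List with `dataset` and `truth` (per-patient `eta` draws, true
#'   scaled parameters, noise-free concentrations).
#' @export
generate_sunitinib_cohort <- function(config = cohort_config_sunitinib(),
                                      seed) {
  stopifnot(inherits(config, "cohort_config_sunitinib"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- config$n_patients
  pop <- config$popset
  K <- pop$iiv
  sex <- stats::rbinom(n, 1L, 0.6)
  age <- .rtrunc_norm(n, 60, 10, 35, 80)
  height <- ifelse(sex == 1, .rtrunc_norm(n, 176, 7, 150, 205),
                   .rtrunc_norm(n, 163, 7, 145, 195))
  weight <- ifelse(sex == 1, .rtrunc_norm(n, 78, 13, 45, 120),
                   .rtrunc_norm(n, 66, 13, 45, 120))
  bsa <- 0.007184 * weight^0.425 * height^0.725
  lbm <- .james_lbm(weight, height, sex)
  fm <- weight - lbm
  miss_wt <- stats::rbinom(n, 1L, config$missing_weight) == 1L
  miss_ht <- stats::rbinom(n, 1L, config$missing_height) == 1L
  miss_bsa <- stats::rbinom(n, 1L, config$missing_bsa) == 1L
  dose <- sample(config$doses, n, replace = TRUE, prob = config$dose_prob)
  eta <- matrix(stats::rnorm(n * length(K), 0,
                             rep(config$omega[K], each = n)), n, length(K),
                dimnames = list(NULL, K))
  n_samp <- sample(1:14, n, replace = TRUE, prob = config$samples_prob)

  on_days <- unlist(lapply(seq_len(config$n_cycles) - 1L,
                           function(cyc) cyc * 42 + 0:(config$days_on - 1)))
  cand_days <- setdiff(seq_len(max(on_days) + 1L) - 1L, 0L)  # day >= 1
  spec <- structural_model("sunitinib")
  ids <- sprintf("S%03d", seq_len(n))
  ev <- list(); tru_obs <- list(); theta_list <- list()
  for (i in seq_len(n)) {
    days <- sort(sample(cand_days, min(n_samp[i], length(cand_days))))
    times <- days * 24 - 0.5  # trough, 30 min before that day's intake
    regimen <- data.frame(time = on_days * 24, amount = dose[i],
                          duration = 0, route = "oral")
    eta_i <- eta[i, ]; names(eta_i) <- K
    theta <- allometric_scale(individual_params(pop, eta_i), weight[i])
    theta_list[[i]] <- theta
    if (config$concentrations) {
      prof <- solve_profile(spec, theta, regimen, times)
      parent <- .prop_noise(prof[, "parent"], config$error_b_parent)
      metab <- .prop_noise(prof[, "metab"], config$error_b_metab)
      tru <- data.frame(patient_id = ids[i], time = times,
                        parent_true = prof[, "parent"],
                        metab_true = prof[, "metab"])
    } else {
      parent <- metab <- rep(NA_real_, length(times))
      tru <- data.frame(patient_id = ids[i], time = times,
                        parent_true = NA_real_, metab_true = NA_real_)
    }
    base <- data.frame(
      ID = ids[i], SEX = sex[i], AGE = age[i],
      WT = if (miss_wt[i]) NA_real_ else weight[i],
      HT = if (miss_ht[i]) NA_real_ else height[i],
      BSA = if (miss_bsa[i]) NA_real_ else bsa[i],
      LBM = lbm[i], FM = fm[i], stringsAsFactors = FALSE)
    n_d <- length(on_days); n_o <- length(times)
    ev[[length(ev) + 1L]] <- cbind(
      data.frame(
        TIME = c(on_days * 24, times, times),
        EVT = c(rep("dose", n_d), rep("obs", 2 * n_o)),
        AMT = c(rep(dose[i], n_d), rep(NA, 2 * n_o)),
        DUR = c(rep(0, n_d), rep(NA, 2 * n_o)),
        DV = c(rep(NA, n_d), parent, metab),
        ANALYTE = c(rep("", n_d), rep("parent", n_o), rep("metab", n_o)),
        BLQ = c(rep(NA, n_d),
                as.numeric(parent < config$blq_threshold),
                rep(0, n_o))),
      base[rep(1L, n_d + 2 * n_o), ])
    tru_obs[[length(tru_obs) + 1L]] <- tru
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  ds <- pk_dataset(events, drug_type = "sunitinib",
                   provenance = "synthetic sunitinib cohort")
  truth <- list(
    patients = data.frame(patient_id = ids, eta, sex = sex, age = age,
                          weight = weight, height = height, bsa = bsa,
                          dose = dose,
                          weight_missing = miss_wt,
                          height_missing = miss_ht,
                          bsa_missing = miss_bsa),
    theta = theta_list,
    observations = do.call(rbind, tru_obs),
    config = config)
  list(dataset = ds, truth = truth)
}

## ---- deterministic preprocessing fixtures --------------------------------

# trims or pads per-patient observations so the total matches `target`
.adjust_obs_total <- function(ev, target, paired = FALSE) {
  count_obs <- function(ev) {
    o <- ev$EVT == "obs" & (!paired | ev$ANALYTE == "parent")
    table(factor(ev$ID[o], levels = unique(ev$ID)))
  }
  repeat {
    cnt <- count_obs(ev)
    total <- sum(cnt)
    if (total == target) break
    if (total > target) {
      id <- names(cnt)[which.max(cnt)]
      rows <- which(ev$ID == id & ev$EVT == "obs" &
                      (!paired | ev$ANALYTE == "parent"))
      if (paired) {
        drop_time <- ev$TIME[rows[length(rows)]]
        ev <- ev[!(ev$ID == id & ev$EVT == "obs" &
                     ev$TIME == drop_time), , drop = FALSE]
      } else {
        ev <- ev[-rows[length(rows)], , drop = FALSE]
      }
    } else {
      id <- names(cnt)[which.min(cnt)]
      rows <- which(ev$ID == id & ev$EVT == "obs")
      tmpl <- ev[rows, , drop = FALSE]
      new_time <- max(ev$TIME[rows]) + 0.25
      if (paired) {
        add <- tmpl[match(c("parent", "metab"), tmpl$ANALYTE), ,
                    drop = FALSE]
      } else {
        add <- tmpl[1L, , drop = FALSE]
      }
      add$TIME <- new_time
      ev <- rbind(ev, add)
    }
  }
  ev <- ev[order(ev$ID, ev$TIME, ev$EVT), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Deterministic preprocessing fixture, intravenous design
#'
#' A synthetic stand-in for the fluorouracil therapeutic-drug-monitoring
#' cohort's raw bookkeeping: 157 patients, 549 observations, of which
#' exactly 8 (on 8 distinct patients) violate the exclusion rules — a mix
#' of below-quantification values and implausible implied clearances,
#' placed far from the thresholds — and exactly one violator is its
#' patient's only observation. Regenerating yields a byte-identical
#' dataset.
#'
#' @return A raw (unfiltered) [pk_dataset()].
#' @export
generate_acceptance_fixture_5fu <- function() {
  cohort <- generate_5fu_cohort(cohort_config_5fu(), seed = 157549L)
  ev <- cohort$dataset$events
  ev <- .adjust_obs_total(ev, 549L)
  obs <- ev$EVT == "obs"
  # keep every non-designated observation safely clear of both rules
  # (BLQ < 0.052 mg/L; implied CL D/(24*C) > 1478 L/h needs C < 0.162
  # at the largest dose)
  ev$DV[obs & ev$DV < 0.18] <- 0.35
  cnt <- table(factor(ev$ID[obs], levels = unique(ev$ID)))
  singles <- names(cnt)[cnt == 1L]
  multis <- names(cnt)[cnt >= 2L]
  stopifnot(length(singles) >= 1L, length(multis) >= 7L)
  viol <- c(singles[1L], multis[1:7])
  last_obs_row <- function(id) {
    r <- which(ev$ID == id & ev$EVT == "obs")
    r[length(r)]
  }
  for (j in seq_along(viol)) {
    r <- last_obs_row(viol[j])
    if (j <= 4L) {             # below-quantification violators
      ev$DV[r] <- 0.040
      ev$BLQ[r] <- 1
    } else {                   # implied-clearance violators
      ev$DV[r] <- 0.070
    }
  }
  ds <- pk_dataset(ev, drug_type = "fu5",
                   provenance = "synthetic preprocessing fixture (5FU-like)")
  stopifnot(length(unique(ev$ID)) == 157L, sum(ev$EVT == "obs") == 549L)
  ds
}

#' Deterministic preprocessing fixture, oral design
#'
#' A synthetic stand-in for the pooled sunitinib cohort's raw
#' bookkeeping: 47 patients, 308 parent plus 308 paired metabolite
#' observations, with exactly 6 parent values below the 0.06 ng/mL
#' quantification limit spread over 5 distinct patients, none of whom
#' loses every sample under filtering. Byte-identical on regeneration.
#'
#' @return A raw (unfiltered) [pk_dataset()].
#' @export
generate_acceptance_fixture_sunitinib <- function() {
  cohort <- generate_sunitinib_cohort(cohort_config_sunitinib(),
                                      seed = 47308L)
  ev <- cohort$dataset$events
  ev <- .adjust_obs_total(ev, 308L, paired = TRUE)
  parent <- ev$EVT == "obs" & ev$ANALYTE == "parent"
  metab <- ev$EVT == "obs" & ev$ANALYTE == "metab"
  ev$DV[parent & ev$DV < 1] <- 10
  ev$DV[metab & ev$DV < 0.5] <- 4
  ev$BLQ[ev$EVT == "obs"] <- 0
  cnt <- table(factor(ev$ID[parent], levels = unique(ev$ID)))
  big <- names(cnt)[cnt >= 3L]
  two <- setdiff(names(cnt)[cnt >= 2L], big[1L])
  stopifnot(length(big) >= 1L, length(two) >= 4L)
  set_blq <- function(ev, id, k, values) {
    r <- which(ev$ID == id & ev$EVT == "obs" & ev$ANALYTE == "parent")
    r <- utils::tail(r, k)
    ev$DV[r] <- values
    ev$BLQ[r] <- 1
    ev
  }
  ev <- set_blq(ev, big[1L], 2L, c(0.040, 0.030))
  for (j in 1:4) ev <- set_blq(ev, two[j], 1L, 0.045)
  ds <- pk_dataset(ev, drug_type = "sunitinib",
                   provenance =
                     "synthetic preprocessing fixture (sunitinib-like)")
  stopifnot(length(unique(ev$ID)) == 47L,
            sum(ev$EVT == "obs" & ev$ANALYTE == "parent") == 308L,
            sum(ev$EVT == "obs" & ev$ANALYTE == "metab") == 308L,
            sum(ev$DV < 0.06 & ev$EVT == "obs" &
                  ev$ANALYTE == "parent", na.rm = TRUE) == 6L)
  ds
}
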