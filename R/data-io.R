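# Event-record dialect: one row per event, comma separated, header mandatory.
# Columns: ID, TIME, EVT (obs|dose), AMT, DUR, DV, ANALYTE (parent|metab),
# BLQ, SEX, AGE, WT, HT, BSA, LBM, FM. Missing numerics are empty cells.
.pk_columns <- c("ID", "TIME", "EVT", "AMT", "DUR", "DV", "ANALYTE", "BLQ",
                 "SEX", "AGE", "WT", "HT", "BSA", "LBM", "FM")
.pk_numeric_columns <- setdiff(.pk_columns, c("ID", "EVT", "ANALYTE"))
.pk_covariate_names <- c("SEX", "AGE", "WT", "HT", "BSA", "LBM", "FM")

#' Construct a longitudinal PK dataset
#'
#' A `pk_dataset` holds a NONMEM-style event-record table (one row per dose
#' or observation event) together with the drug type that fixes its units
#' and analyte set. Concentrations are mg/L for the intravenous fluorouracil
#' design (`"fu5"`) and ng/mL for the oral sunitinib design
#' (`"sunitinib"`, parent and metabolite analytes). Time is hours since the
#' patient's first dose. Static covariates (sex coded 1 = male / 0 = female,
#' age in years, weight kg, height cm, body surface area m^2, lean body mass
#' kg, fat mass kg) are repeated on every row of a patient; missing values
#' are `NA`, never sentinel codes.
#'
#' @param events data frame with columns `ID, TIME, EVT, AMT, DUR, DV,
#'   ANALYTE, BLQ, SEX, AGE, WT, HT, BSA, LBM, FM`.
#' @param drug_type `"fu5"` or `"sunitinib"`.
#' @param provenance free-text note on where the records came from.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(events, drug_type = c("fu5", "sunitinib"),
                       provenance = "") {
  drug_type <- match.arg(drug_type)
  missing_cols <- setdiff(.pk_columns, names(events))
  if (length(missing_cols) > 0L)
    stop("event table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  events <- events[, .pk_columns]
  events$ID <- as.character(events$ID)
  events$EVT <- as.character(events$EVT)
  events$ANALYTE <- as.character(events$ANALYTE)
  bad_evt <- !events$EVT %in% c("obs", "dose")
  if (any(bad_evt))
    stop("EVT must be 'obs' or 'dose' (row ", which(bad_evt)[1L], ")",
         call. = FALSE)
  obs <- events$EVT == "obs"
  if (any(events$TIME < 0, na.rm = TRUE))
    stop("negative TIME encountered", call. = FALSE)
  if (any(obs & !is.na(events$DV) & events$DV < 0))
    stop("negative concentration (DV) encountered", call. = FALSE)
  if (drug_type == "fu5" && any(events$ANALYTE[obs] == "metab"))
    stop("metabolite observations are only valid for sunitinib datasets",
         call. = FALSE)
  dose <- events$EVT == "dose"
  if (any(dose & (is.na(events$AMT) | events$AMT <= 0)))
    stop("dose rows must carry a positive AMT", call. = FALSE)
  structure(list(events = events, drug_type = drug_type,
                 provenance = provenance),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  ev <- x$events
  n_obs <- sum(ev$EVT == "obs")
  cat("<pk_dataset> drug:", x$drug_type,
      "| patients:", length(unique(ev$ID)),
      "| observations:", n_obs,
      "| dose events:", sum(ev$EVT == "dose"), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read an event-record file
#'
#' Parses the comma-separated event-record dialect documented in
#' [pk_dataset()]. Empty cells in numeric columns become `NA` (a missing
#' mask, never a sentinel value); any other non-numeric content is a parse
#' error that names the offending row.
#'
#' @param path file path.
#' @inheritParams pk_dataset
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, drug_type = c("fu5", "sunitinib")) {
  drug_type <- match.arg(drug_type)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.pk_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in .pk_numeric_columns) {
    v <- trimws(raw[[cl]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L)
      stop("non-numeric value '", v[bad[1L]], "' in column ", cl,
           " at data row ", bad[1L], call. = FALSE)
    raw[[cl]] <- num
  }
  pk_dataset(raw, drug_type = drug_type, provenance = path)
}

#' Write an event-record file
#'
#' Inverse of [read_pk_dataset()]: numeric fields are written with full
#' (17 significant digit) precision so a read/write round trip reproduces
#' every value and every missing mask exactly.
#'
#' @param ds a [pk_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  out <- ev
  for (cl in .pk_numeric_columns) {
    v <- ev[[cl]]
    s <- ifelse(is.na(v), "", sprintf("%.17g", v))
    out[[cl]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split a dataset into per-patient records
#'
#' @param ds a [pk_dataset()].
#' @return A named list with one element per patient: `patient_id`,
#'   `covariates` (named numeric vector, `NA` where missing), `mask`
#'   (1 = observed), `doses` (data frame `time, amount, duration, route`) and
#'   `observations` (data frame `time, value, analyte, blq`).
#' @export
pk_patients <- function(ds) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  ids <- unique(ev$ID)
  out <- lapply(ids, function(id) {
    rows <- ev[ev$ID == id, , drop = FALSE]
    cov <- vapply(.pk_covariate_names, function(cl) {
      v <- rows[[cl]]
      v <- v[!is.na(v)]
      if (length(v) > 0L) v[1L] else NA_real_
    }, numeric(1))
    dr <- rows[rows$EVT == "dose", , drop = FALSE]
    if (nrow(dr) == 0L)
      stop("patient ", id, " has no dose event", call. = FALSE)
    doses <- data.frame(
      time = dr$TIME, amount = dr$AMT,
      duration = ifelse(is.na(dr$DUR), 0, dr$DUR),
      route = ifelse(!is.na(dr$DUR) & dr$DUR > 0, "iv_infusion", "oral"),
      stringsAsFactors = FALSE)
    orow <- rows[rows$EVT == "obs", , drop = FALSE]
    observations <- data.frame(
      time = orow$TIME, value = orow$DV, analyte = orow$ANALYTE,
      blq = ifelse(is.na(orow$BLQ), 0, orow$BLQ),
      stringsAsFactors = FALSE)
    list(patient_id = id, covariates = cov,
         mask = as.numeric(!is.na(cov)),
         doses = doses, observations = observations)
  })
  names(out) <- ids
  out
}

# governing dose for each observation row: latest dose at or before the
# observation time, per patient
.governing_dose <- function(ev) {
  obs_idx <- which(ev$EVT == "obs")
  gov <- rep(NA_integer_, length(obs_idx))
  for (j in seq_along(obs_idx)) {
    i <- obs_idx[j]
    cand <- which(ev$EVT == "dose" & ev$ID == ev$ID[i] & ev$TIME <= ev$TIME[i])
    if (length(cand) == 0L)
      stop("observation at t=", ev$TIME[i], " h for patient ", ev$ID[i],
           " has no governing dose", call. = FALSE)
    gov[j] <- cand[which.max(ev$TIME[cand])]
  }
  list(obs = obs_idx, dose = gov)
}

.drop_empty_patients <- function(ev) {
  keep_ids <- unique(ev$ID[ev$EVT == "obs"])
  ev[ev$ID %in% keep_ids, , drop = FALSE]
}

#' Exclusion filter for the intravenous fluorouracil design
#'
#' Removes implausible steady-state samples: concentrations below the assay
#' quantification limit, and concentrations implying a physiologically
#' impossible clearance. The implied clearance uses the steady-state
#' identity CL = D / (IT * C) with dose D (mg), infusion duration IT (h) and
#' concentration C (mg/L), taken from each observation's governing dose
#' event. Patients left without any observation are removed entirely.
#'
#' @param ds a `"fu5"` [pk_dataset()]; concentrations in mg/L.
#' @param blq_threshold lower limit of quantification in ng/mL (default 52).
#' @param cl_threshold implied-clearance ceiling in L/h (default 1478).
#' @return A list: `dataset` (filtered [pk_dataset()]) and `report` with raw
#'   and kept counts, per-reason exclusion counts and the excluded fraction.
#' @export
apply_exclusions_5fu <- function(ds, blq_threshold = 52,
                                 cl_threshold = 1478) {
  stopifnot(inherits(ds, "pk_dataset"))
  if (ds$drug_type != "fu5")
    stop("apply_exclusions_5fu expects a fu5 dataset", call. = FALSE)
  ev <- ds$events
  gv <- .governing_dose(ev)
  dv <- ev$DV[gv$obs]
  d_mg <- ev$AMT[gv$dose]
  it_h <- ev$DUR[gv$dose]
  if (any(is.na(it_h) | it_h <= 0))
    stop("fu5 governing doses must be infusions with DUR > 0", call. = FALSE)
  blq <- !is.na(dv) & dv < blq_threshold / 1000  # ng/mL -> mg/L
  implied_cl <- d_mg / (it_h * dv)
  high_cl <- !is.na(dv) & dv > 0 & implied_cl > cl_threshold
  drop <- blq | high_cl
  reason <- ifelse(blq, "blq", ifelse(high_cl, "implied_clearance", ""))
  n_pat_raw <- length(unique(ev$ID))
  keep_rows <- rep(TRUE, nrow(ev))
  keep_rows[gv$obs[drop]] <- FALSE
  ev2 <- .drop_empty_patients(ev[keep_rows, , drop = FALSE])
  out <- pk_dataset(ev2, drug_type = "fu5", provenance = ds$provenance)
  report <- list(
    drug_type = "fu5",
    n_obs_raw = length(gv$obs),
    n_obs_kept = sum(out$events$EVT == "obs"),
    n_excluded = sum(drop),
    excluded_fraction = sum(drop) / length(gv$obs),
    n_excluded_by_reason = c(blq = sum(blq),
                             implied_clearance = sum(high_cl & !blq)),
    n_patients_raw = n_pat_raw,
    n_patients_kept = length(unique(out$events$ID)),
    excluded_patient_ids = unique(ev$ID[gv$obs[drop]]))
  list(dataset = out, report = report)
}

#' Exclusion filter for the oral sunitinib design
#'
#' Removes parent-drug observations below the lower limit of quantification
#' together with the metabolite observation paired at the same (patient,
#' time), so the parent and metabolite counts stay equal.
#'
#' @param ds a `"sunitinib"` [pk_dataset()]; concentrations in ng/mL.
#' @param blq_threshold quantification limit in ng/mL (default 0.06).
#' @return A list: `dataset` and `report` (counts per analyte, excluded
#'   fraction of parent samples, patients affected).
#' @export
apply_exclusions_sunitinib <- function(ds, blq_threshold = 0.06) {
  stopifnot(inherits(ds, "pk_dataset"))
  if (ds$drug_type != "sunitinib")
    stop("apply_exclusions_sunitinib expects a sunitinib dataset",
         call. = FALSE)
  ev <- ds$events
  obs <- ev$EVT == "obs"
  parent <- obs & ev$ANALYTE == "parent"
  metab <- obs & ev$ANALYTE == "metab"
  blq_parent <- parent & !is.na(ev$DV) & ev$DV < blq_threshold
  key <- paste(ev$ID, ev$TIME, sep = "@")
  blq_keys <- key[blq_parent]
  drop <- blq_parent | (metab & key %in% blq_keys)
  n_pat_raw <- length(unique(ev$ID))
  ev2 <- .drop_empty_patients(ev[!drop, , drop = FALSE])
  out <- pk_dataset(ev2, drug_type = "sunitinib", provenance = ds$provenance)
  report <- list(
    drug_type = "sunitinib",
    n_parent_raw = sum(parent),
    n_metab_raw = sum(metab),
    n_parent_kept = sum(out$events$EVT == "obs" &
                          out$events$ANALYTE == "parent"),
    n_metab_kept = sum(out$events$EVT == "obs" &
                         out$events$ANALYTE == "metab"),
    n_excluded_parent = sum(blq_parent),
    n_excluded_metab = sum(drop) - sum(blq_parent),
    excluded_fraction_parent = sum(blq_parent) / sum(parent),
    n_patients_raw = n_pat_raw,
    n_patients_kept = length(unique(out$events$ID)),
    excluded_patient_ids = unique(ev$ID[blq_parent]))
  list(dataset = out, report = report)
}

#' Patient-level repeated k-fold cross-validation splits
#'
#' Generates `n_repeats` independent shuffles of the patients, each
#' partitioned into `n_folds` test folds; all records of a patient stay on
#' one side of every split (an 80/20 train/test split for 5 folds).
#'
#' @param ds a [pk_dataset()], or a character vector of patient ids.
#' @param n_repeats number of independent repeats (default 10).
#' @param n_folds folds per repeat (default 5).
#' @param seed integer seed; the split list is fully determined by it.
#' @return A list of splits, each a list with `repeat_index`, `fold_index`,
#'   `train_patient_ids`, `test_patient_ids`.
#' @export
split_cv <- function(ds, n_repeats = 10, n_folds = 5, seed) {
  ids <- if (inherits(ds, "pk_dataset")) unique(ds$events$ID)
         else as.character(ds)
  n <- length(ids)
  if (n < n_folds)
    stop("need at least ", n_folds, " patients for ", n_folds,
         "-fold splitting, got ", n, call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  splits <- list()
  for (r in seq_len(n_repeats)) {
    perm <- sample(ids)
    fold_of <- rep(seq_len(n_folds), length.out = n)
    for (f in seq_len(n_folds)) {
      test <- perm[fold_of == f]
      splits[[length(splits) + 1L]] <- list(
        repeat_index = r, fold_index = f,
        train_patient_ids = sort(setdiff(ids, test)),
        test_patient_ids = sort(test))
    }
  }
  splits
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Impute missing body weight by sex
#'
#' Fills missing weights in `target` with the mean observed weight of the
#' matching sex computed on `train` only; `target` statistics never enter
#' the means (no train/test leakage) and `train` is never altered.
#'
#' @param train training [pk_dataset()] (source of the sex-specific means).
#' @param target dataset whose missing weights are filled (may be `train`
#'   itself).
#' @return `target` with `WT` imputed.
#' @export
impute_weight_by_sex <- function(train, target) {
  stopifnot(inherits(train, "pk_dataset"), inherits(target, "pk_dataset"))
  tr <- pk_patients(train)
  wt <- vapply(tr, function(p) p$covariates[["WT"]], numeric(1))
  sex <- vapply(tr, function(p) p$covariates[["SEX"]], numeric(1))
  means <- tapply(wt[!is.na(wt) & !is.na(sex)],
                  sex[!is.na(wt) & !is.na(sex)], mean)
  ev <- target$events
  for (id in unique(ev$ID)) {
    rows <- ev$ID == id
    if (all(is.na(ev$WT[rows]))) {
      s <- ev$SEX[rows]
      s <- s[!is.na(s)]
      if (length(s) == 0L)
        stop("patient ", id, " needs weight imputation but has no sex",
             call. = FALSE)
      key <- as.character(s[1L])
      if (!key %in% names(means))
        stop("no observed training weights for sex ", key, call. = FALSE)
      ev$WT[rows] <- means[[key]]
    }
  }
  pk_dataset(ev, drug_type = target$drug_type,
             provenance = target$provenance)
}
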