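# Variational objective: negative evidence lower bound = reconstruction
# negative log-likelihood under a proportional residual-error model plus
# the KL divergence of each random-effect posterior from its N(0, lambda^2)
# prior, averaged over patients (or, for the steady-state intravenous
# design, over measurement samples).

#' Loss configuration
#'
#' @param lambda prior scale of the random effects.
#' @param error_model `"prop_to_pred"` (residual SD `b * yhat`, default) or
#'   `"prop_to_obs"` (residual variance `b^2 * y`).
#' @param b proportional residual-error coefficient.
#' @param learn_b whether `b` is learned (in log domain) during fitting;
#'   when `TRUE` the training objective also carries the Gaussian
#'   log-normalizer `sum(log eps)`, without which `b` is unidentifiable.
#' @param kl_weight multiplier on the KL term (warm-up schedules set it
#'   below 1 early in training).
#' @param n_mc Monte-Carlo samples of eta per datum per step.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(lambda = 1, error_model = c("prop_to_pred",
                                                    "prop_to_obs"),
                        b = 0.2, learn_b = TRUE, kl_weight = 1, n_mc = 1) {
  error_model <- match.arg(error_model)
  stopifnot(lambda > 0, b > 0, n_mc >= 1)
  structure(list(lambda = lambda, error_model = error_model, b = b,
                 learn_b = learn_b, kl_weight = kl_weight, n_mc = n_mc),
            class = "loss_config")
}

#' KL divergence of a Gaussian posterior from a centered Gaussian prior
#'
#' `KL(N(mu, sigma2) || N(0, lambda2)) =
#'  0.5 * (sigma2/lambda2 + mu^2/lambda2 - 1 + log(lambda2/sigma2))`,
#' nonnegative, zero iff the two distributions coincide. Vectorized.
#'
#' @param mu posterior mean(s).
#' @param sigma2 posterior variance(s), > 0.
#' @param lambda2 prior variance, > 0.
#' @return KL divergence, same shape as `mu`.
#' @export
kl_gaussian <- function(mu, sigma2, lambda2) {
  if (any(sigma2 <= 0) || any(lambda2 <= 0))
    stop("variances must be positive", call. = FALSE)
  0.5 * (sigma2 / lambda2 + mu^2 / lambda2 - 1 + log(lambda2 / sigma2))
}

#' Reconstruction term of the variational loss
#'
#' Sum over observations of `(y - yhat)^2 / (2 * eps^2)` with a
#' proportional error: `eps = b * yhat` under `"prop_to_pred"`,
#' `eps^2 = b^2 * y` under `"prop_to_obs"`.
#'
#' @param y observed concentrations.
#' @param yhat model-predicted concentrations (positive under
#'   `"prop_to_pred"`).
#' @param cfg a [loss_config()].
#' @return Scalar reconstruction term.
#' @export
reconstruction_nll <- function(y, yhat, cfg) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  if (cfg$error_model == "prop_to_pred") {
    if (any(yhat <= 0))
      stop("predictions must be positive under prop_to_pred",
           call. = FALSE)
    sum((y - yhat)^2 / (2 * cfg$b^2 * yhat^2))
  } else {
    if (any(y <= 0))
      stop("observations must be positive under prop_to_obs",
           call. = FALSE)
    sum((y - yhat)^2 / (2 * cfg$b^2 * y))
  }
}

# log-normalizer of the Gaussian residual density, needed when b is learned
.recon_lognorm <- function(y, yhat, cfg) {
  if (cfg$error_model == "prop_to_pred") sum(log(cfg$b * yhat))
  else sum(0.5 * log(cfg$b^2 * y))
}

#' Evaluate the negative ELBO on a dataset
#'
#' For every sampling unit (a measurement sample for the steady-state
#' intravenous design; a patient for the oral design): encode to
#' `(mu, log sigma^2)`, draw `eta = mu + sigma * z` with `z ~ N(0,1)`,
#' build individual parameters, predict concentrations with the structural
#' model, and accumulate the reconstruction term plus the per-parameter KL
#' divergences. Returns the mean over units and its decomposition.
#'
#' @param ds a [pk_dataset()] (preprocessed: exclusions applied, weight
#'   imputed where the structural model needs it).
#' @param encoder a `vampk_encoder`.
#' @param popset a [pop_parameters()] set.
#' @param cfg a [loss_config()].
#' @param seed integer seed for the reparametrized draws.
#' @param rtol,atol structural-solver tolerances (oral design).
#' @return A list `total`, `reconstruction`, `kl` (and `lognorm` when
#'   `cfg$learn_b`), with `total` equal to the sum of the parts.
#' @export
elbo_loss <- function(ds, encoder, popset, cfg, seed,
                      rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(ds, "pk_dataset"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (ds$drug_type == "fu5") {
    sm <- .fu5_samples(ds)
    fw <- .enc5_forward(encoder, sm$X, sm$mask, training = FALSE)
    n <- nrow(sm$X)
    z <- stats::rnorm(n)
    sig <- exp(fw$log_var[, 1L] / 2)
    eta <- fw$mu[, 1L] + sig * z
    tv_cl <- popset$tv[["CL"]]
    yhat <- css_5fu(sm$D, sm$IT, tv_cl * exp(eta))
    recon <- vapply(seq_len(n), function(i)
      reconstruction_nll(sm$y[i], yhat[i], cfg), numeric(1))
    kl <- kl_gaussian(fw$mu[, 1L], sig^2, cfg$lambda^2)
    lognorm <- if (cfg$learn_b)
      vapply(seq_len(n), function(i)
        .recon_lognorm(sm$y[i], yhat[i], cfg), numeric(1)) else 0
    out <- list(total = mean(recon + cfg$kl_weight * kl + lognorm),
                reconstruction = mean(recon),
                kl = mean(cfg$kl_weight * kl))
    if (cfg$learn_b) out$lognorm <- mean(lognorm)
    out
  } else {
    pats <- pk_patients(ds)
    spec <- structural_model("sunitinib")
    per <- lapply(pats, function(p) {
      fw <- .encsun_forward(encoder, .sun_static(p)$x, .sun_static(p)$mask,
                            .sun_seq(p)$time, .sun_seq(p)$values,
                            training = FALSE)
      z <- stats::rnorm(length(encoder$K))
      sig <- exp(fw$log_var / 2)
      eta <- fw$mu + sig * z
      names(eta) <- encoder$K
      data_term <- .sun_data_term(p, eta, popset, cfg, spec, rtol, atol)
      kl <- sum(kl_gaussian(fw$mu, sig^2, cfg$lambda^2))
      c(recon = data_term$recon, kl = kl, lognorm = data_term$lognorm)
    })
    per <- do.call(rbind, per)
    out <- list(
      total = mean(per[, "recon"] + cfg$kl_weight * per[, "kl"] +
                     (if (cfg$learn_b) per[, "lognorm"] else 0)),
      reconstruction = mean(per[, "recon"]),
      kl = mean(cfg$kl_weight * per[, "kl"]))
    if (cfg$learn_b) out$lognorm <- mean(per[, "lognorm"])
    out
  }
}

# data term (reconstruction + optional log-normalizer) for one oral-design
# patient at a given eta
.sun_data_term <- function(p, eta, popset, cfg, spec, rtol, atol) {
  theta <- individual_params(popset, eta)
  theta <- allometric_scale(theta, p$covariates[["WT"]])
  obs <- p$observations
  times <- sort(unique(obs$time))
  pred <- solve_profile(spec, theta, p$doses, times, rtol, atol)
  yhat <- pred[match(obs$time, times) +
                 (match(obs$analyte, colnames(pred)) - 1L) * length(times)]
  yhat <- pmax(yhat, 1e-12)
  list(recon = reconstruction_nll(obs$value, yhat, cfg),
       lognorm = if (cfg$learn_b) .recon_lognorm(obs$value, yhat, cfg)
                 else 0,
       yhat = yhat)
}

## ---- sample extraction helpers -------------------------------------------

# steady-state measurement samples for the intravenous design
.fu5_samples <- function(ds) {
  ev <- ds$events
  gv <- .governing_dose(ev)
  o <- gv$obs; d <- gv$dose
  X <- cbind(CONC = ev$DV[o], DOSE = ev$AMT[d], WT = ev$WT[o],
             LBM = ev$LBM[o], FM = ev$FM[o], BSA = ev$BSA[o],
             AGE = ev$AGE[o], SEX = ev$SEX[o], HT = ev$HT[o])
  mask <- (!is.na(X)) * 1
  X[is.na(X)] <- 0
  list(X = X, mask = mask, y = ev$DV[o], D = ev$AMT[d], IT = ev$DUR[d],
       patient_id = ev$ID[o], time = ev$TIME[o])
}

.sun_static <- function(p) {
  x <- p$covariates[.encsun_static]
  mask <- as.numeric(!is.na(x))
  x[is.na(x)] <- 0
  list(x = as.numeric(x), mask = mask)
}

# paired (time, parent, metabolite) sequence for the recurrent block
.sun_seq <- function(p) {
  obs <- p$observations
  times <- sort(unique(obs$time))
  parent <- obs$value[match(paste(times, "parent"),
                            paste(obs$time, obs$analyte))]
  metab <- obs$value[match(paste(times, "metab"),
                           paste(obs$time, obs$analyte))]
  vals <- cbind(parent = parent, metab = metab)
  vals[is.na(vals)] <- 0
  list(time = times, values = vals)
}
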