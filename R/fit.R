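# Model fitting: gradient-based minimization of the negative ELBO over the
# encoder weights, the learned typical values (log domain) and, optionally,
# the residual-error coefficient. The intravenous steady-state design
# trains fully vectorized over measurement samples with an analytic chain
# through the closed-form steady-state concentration; the oral design
# trains per patient, with analytic encoder gradients chained to a
# finite-difference sensitivity of the ODE data term with respect to the
# sampled random effects and learned typical values.

#' Fitting control parameters
#'
#' @param epochs maximum training epochs.
#' @param lr Adam step size.
#' @param clip global gradient-norm clip.
#' @param val_fraction fraction of patients held out for early stopping
#'   (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param weight_decay decoupled L2 decay applied to the encoder weights
#'   each step (never to typical values or the error coefficient).
#' @param lambda prior scale of the random effects.
#' @param error_model,b_init,learn_b residual-error model, see
#'   [loss_config()].
#' @param kl_warmup epochs over which the KL weight ramps 0 to 1.
#' @param encoder an [encoder_config()].
#' @param rtol,atol structural-solver tolerances (oral design training).
#' @param fd_step finite-difference step for the ODE sensitivity (oral
#'   design).
#' @param verbose print progress every 50 epochs.
#' @return A list of class `vampk_control`.
#' @export
vampk_control <- function(epochs = 1000, lr = 1e-3, clip = 1,
                          val_fraction = 0.1, patience = 200,
                          weight_decay = 1e-3,
                          lambda = 1, error_model = "prop_to_pred",
                          b_init = 0.2, learn_b = TRUE, kl_warmup = 0,
                          encoder = encoder_config(),
                          rtol = 1e-6, atol = 1e-8, fd_step = 1e-4,
                          verbose = FALSE) {
  structure(list(epochs = epochs, lr = lr, clip = clip,
                 val_fraction = val_fraction, patience = patience,
                 weight_decay = weight_decay,
                 lambda = lambda, error_model = error_model,
                 b_init = b_init, learn_b = learn_b,
                 kl_warmup = kl_warmup, encoder = encoder,
                 rtol = rtol, atol = atol, fd_step = fd_step,
                 verbose = verbose),
            class = "vampk_control")
}

#' Fit the variational amortized mixed-effects PK model
#'
#' Trains the drug-specific encoder and the learned typical values by
#' minimizing the negative evidence lower bound with reparametrized
#' sampling of the random effects (one draw per unit per step), Adam
#' updates and global gradient-norm clipping. The run is fully determined
#' by `seed`.
#'
#' @param data a preprocessed [pk_dataset()] (exclusion filters applied;
#'   for the oral design, weight imputed so allometric scaling is defined).
#' @param drug `"fu5"` or `"sunitinib"`; defaults to the dataset's type.
#' @param control a [vampk_control()].
#' @param seed integer seed (mandatory).
#' @param popset starting [pop_parameters()]; defaults to
#'   [default_popset()].
#' @return An object of class `vampk`: the trained encoder, the updated
#'   population parameter set, the loss trajectory (`$trace`), the final
#'   loss decomposition (`$loss`) and the configuration snapshot.
#' @seealso [predict.vampk()], [simulate.vampk()], [posterior_eta()]
#' @export
vampk <- function(data, drug = data$drug_type, control = vampk_control(),
                  seed, popset = NULL) {
  stopifnot(inherits(data, "pk_dataset"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (drug != data$drug_type)
    stop("drug does not match the dataset's drug_type", call. = FALSE)
  if (is.null(popset))
    popset <- default_popset(drug, lambda = control$lambda,
                             error_b = control$b_init)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  fit <- if (drug == "fu5") .fit_fu5(data, control, popset)
         else .fit_sunitinib(data, control, popset)
  fit$seed <- seed
  fit$data <- data
  fit$call <- match.call()
  class(fit) <- "vampk"
  fit
}

## ---- intravenous steady-state design -------------------------------------

.fit_fu5 <- function(data, control, popset) {
  sm <- .fu5_samples(data)
  n <- length(sm$y)
  ids <- unique(sm$patient_id)

  # patient-level validation split for early stopping
  n_val <- floor(control$val_fraction * length(ids))
  val_ids <- if (n_val >= 1) sample(ids, n_val) else character()
  val <- sm$patient_id %in% val_ids
  tr <- !val
  if (sum(tr) == 0L) stop("no training samples left", call. = FALSE)

  norm <- .norm_stats(.enc5_log(sm$X[tr, , drop = FALSE],
                                sm$mask[tr, , drop = FALSE]),
                      sm$mask[tr, , drop = FALSE])
  enc <- .encoder_init("fu5", popset$iiv, control$encoder, norm)
  cfg <- loss_config(lambda = control$lambda,
                     error_model = control$error_model,
                     b = control$b_init, learn_b = control$learn_b)

  params <- list(enc = enc$params,
                 log_tv = log(popset$tv[popset$learned]))
  if (control$learn_b) params$log_b <- log(control$b_init)
  opt <- .adam_init(params)

  Xtr <- sm$X[tr, , drop = FALSE]; Mtr <- sm$mask[tr, , drop = FALSE]
  ytr <- sm$y[tr]; Dtr <- sm$D[tr]; ITtr <- sm$IT[tr]
  ntr <- sum(tr)
  lam2 <- control$lambda^2

  trace <- matrix(NA_real_, control$epochs, 4,
                  dimnames = list(NULL, c("total", "reconstruction", "kl",
                                          "val")))
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L

  # fixed validation draw: the same ELBO as in training, evaluated with a
  # frozen z so the early-stopping criterion is deterministic across epochs
  z_val <- stats::rnorm(sum(val))
  eval_loss <- function(params, idx) {
    enc$params <- params$enc
    b <- if (control$learn_b) exp(params$log_b) else control$b_init
    fw <- .enc5_forward(enc, sm$X[idx, , drop = FALSE],
                        sm$mask[idx, , drop = FALSE], training = FALSE)
    sig <- exp(fw$log_var[, 1L] / 2)
    eta <- fw$mu[, 1L] + sig * z_val
    tv_cl <- exp(params$log_tv[["CL"]])
    yhat <- css_5fu(sm$D[idx], sm$IT[idx], tv_cl * exp(eta))
    recon <- (sm$y[idx] - yhat)^2 / (2 * b^2 * yhat^2)
    kl <- kl_gaussian(fw$mu[, 1L], sig^2, lam2)
    lognorm <- if (control$learn_b) log(b * yhat) else 0
    mean(recon + kl + lognorm)
  }

  for (epoch in seq_len(control$epochs)) {
    klw <- if (control$kl_warmup > 0) min(1, epoch / control$kl_warmup)
           else 1
    enc$params <- params$enc
    fw <- .enc5_forward(enc, Xtr, Mtr, training = TRUE)
    mu <- fw$mu[, 1L]; lv <- fw$log_var[, 1L]
    sig <- exp(lv / 2)
    z <- stats::rnorm(ntr)
    eta <- mu + sig * z
    b <- if (control$learn_b) exp(params$log_b) else control$b_init
    tv_cl <- exp(params$log_tv[["CL"]])
    yhat <- (Dtr / ITtr) / (tv_cl * exp(eta))
    res <- ytr - yhat

    if (control$error_model == "prop_to_pred") {
      recon <- res^2 / (2 * b^2 * yhat^2)
      drecon_dyhat <- -res / (b^2 * yhat^2) - res^2 / (b^2 * yhat^3)
      dlognorm_dyhat <- if (control$learn_b) 1 / yhat else 0
      dlogb <- if (control$learn_b) mean(-2 * recon + 1) else NULL
      lognorm <- if (control$learn_b) log(b * yhat) else rep(0, ntr)
    } else {
      recon <- res^2 / (2 * b^2 * ytr)
      drecon_dyhat <- -res / (b^2 * ytr)
      dlognorm_dyhat <- 0
      dlogb <- if (control$learn_b) mean(-2 * recon + 1) else NULL
      lognorm <- if (control$learn_b) 0.5 * log(b^2 * ytr) else rep(0, ntr)
    }
    kl <- kl_gaussian(mu, sig^2, lam2)
    total <- mean(recon + lognorm + klw * kl)

    if (!is.finite(total))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)

    ddata_dyhat <- drecon_dyhat + dlognorm_dyhat
    ddata_deta <- ddata_dyhat * (-yhat)     # dyhat/deta = -yhat
    dmu <- (ddata_deta + klw * mu / lam2) / ntr
    dlv <- (ddata_deta * sig * z / 2 +
              klw * 0.5 * (sig^2 / lam2 - 1)) / ntr
    genc <- .enc5_backward(enc, fw$cache, matrix(dmu, ncol = 1L),
                           matrix(dlv, ncol = 1L))
    grads <- list(enc = genc,
                  log_tv = c(CL = mean(ddata_deta)))
    if (control$learn_b) grads$log_b <- dlogb
    grads <- .clip_grads(grads, control$clip)

    st <- .adam_step(params, grads, opt, lr = control$lr)
    params <- st$params; opt <- st$state
    if (control$weight_decay > 0)
      params$enc <- .par_scale(params$enc,
                               1 - control$lr * control$weight_decay)

    trace[epoch, 1:3] <- c(total, mean(recon), mean(klw * kl))

    if (length(val_ids) > 0) {
      vl <- eval_loss(params, which(val))
      trace[epoch, 4] <- vl
      if (vl < best$loss - 1e-8) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
    if (control$verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d: loss %.4f", epoch, total))
  }
  if (length(val_ids) > 0 && best$epoch > 0L) params <- best$params

  enc$params <- params$enc
  popset$tv[popset$learned] <- exp(params$log_tv)
  if (control$learn_b) popset$error_b <- exp(params$log_b)
  cfg$b <- popset$error_b
  trace <- as.data.frame(trace[!is.na(trace[, 1L]), , drop = FALSE])
  trace$epoch <- seq_len(nrow(trace))
  final <- .final_decomposition(trace)
  list(drug_type = "fu5", encoder = enc, popset = popset,
       control = control, loss = final, trace = trace,
       val_patient_ids = sort(val_ids), n_samples = n)
}

.final_decomposition <- function(trace) {
  last <- trace[nrow(trace), ]
  list(total = last$total, reconstruction = last$reconstruction,
       kl = last$kl,
       other = last$total - last$reconstruction - last$kl)
}

## ---- oral parent-metabolite design ---------------------------------------

.fit_sunitinib <- function(data, control, popset) {
  pats <- pk_patients(data)
  wts <- vapply(pats, function(p) p$covariates[["WT"]], numeric(1))
  if (any(is.na(wts)))
    stop("missing weight for patient(s) ",
         paste(names(pats)[is.na(wts)], collapse = ", "),
         "; impute before fitting (impute_weight_by_sex)", call. = FALSE)
  ids <- names(pats)
  n_val <- floor(control$val_fraction * length(ids))
  val_ids <- if (n_val >= 1) sample(ids, n_val) else character()
  tr_ids <- setdiff(ids, val_ids)

  Xs <- do.call(rbind, lapply(pats[tr_ids], function(p) .sun_static(p)$x))
  Ms <- do.call(rbind, lapply(pats[tr_ids], function(p) .sun_static(p)$mask))
  seq_all <- do.call(rbind, lapply(pats[tr_ids],
                                   function(p) .sun_seq(p)$values))
  norm <- list(static = .norm_stats(Xs, Ms),
               seq = .norm_stats(.seq_log(seq_all),
                                 matrix(1, nrow(seq_all), ncol(seq_all))))
  enc <- .encoder_init("sunitinib", popset$iiv, control$encoder, norm)
  cfg <- loss_config(lambda = control$lambda,
                     error_model = control$error_model,
                     b = control$b_init, learn_b = control$learn_b)
  spec <- structural_model("sunitinib")
  K <- popset$iiv
  lam2 <- control$lambda^2

  params <- list(enc = enc$params,
                 log_tv = log(popset$tv[popset$learned]))
  if (control$learn_b) params$log_b <- log(control$b_init)
  opt <- .adam_init(params)
  h <- control$fd_step
  # frozen validation draw (see the intravenous fit)
  z_val <- matrix(stats::rnorm(length(val_ids) * length(K)),
                  max(1L, length(val_ids)), length(K))

  patient_terms <- function(p, params, eta, cfg_b) {
    pop <- popset
    pop$tv[popset$learned] <- exp(params$log_tv)
    cfg$b <- cfg_b
    .sun_data_term(p, eta, pop, cfg, spec, control$rtol, control$atol)
  }

  trace <- matrix(NA_real_, control$epochs, 4,
                  dimnames = list(NULL, c("total", "reconstruction", "kl",
                                          "val")))
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  extra_tv <- setdiff(popset$learned, K)  # learned TVs without IIV

  for (epoch in seq_len(control$epochs)) {
    klw <- if (control$kl_warmup > 0) min(1, epoch / control$kl_warmup)
           else 1
    enc$params <- params$enc
    b <- if (control$learn_b) exp(params$log_b) else control$b_init
    grad_sum <- NULL
    tot <- rec <- klt <- 0
    for (id in tr_ids) {
      p <- pats[[id]]
      st <- .sun_static(p); sq <- .sun_seq(p)
      fw <- .encsun_forward(enc, st$x, st$mask, sq$time, sq$values,
                            training = TRUE)
      sig <- exp(fw$log_var / 2)
      z <- stats::rnorm(length(K))
      eta <- fw$mu + sig * z
      names(eta) <- K
      base <- patient_terms(p, params, eta, b)
      data0 <- base$recon + (if (control$learn_b) base$lognorm else 0)

      # sensitivity of the data term to each sampled eta_k (also the
      # gradient of log TV_k for k in K, since theta_k = TV_k * exp(eta_k))
      deta <- numeric(length(K)); names(deta) <- K
      for (k in K) {
        ep <- eta; ep[k] <- ep[k] + h
        em <- eta; em[k] <- em[k] - h
        tp <- patient_terms(p, params, ep, b)
        tm <- patient_terms(p, params, em, b)
        dp <- tp$recon + (if (control$learn_b) tp$lognorm else 0)
        dm <- tm$recon + (if (control$learn_b) tm$lognorm else 0)
        deta[k] <- (dp - dm) / (2 * h)
      }
      dtv_extra <- numeric(length(extra_tv)); names(dtv_extra) <- extra_tv
      for (k in extra_tv) {
        pp <- params; pp$log_tv[k] <- pp$log_tv[k] + h
        pm <- params; pm$log_tv[k] <- pm$log_tv[k] - h
        tp <- patient_terms(p, pp, eta, b)
        tm <- patient_terms(p, pm, eta, b)
        dp <- tp$recon + (if (control$learn_b) tp$lognorm else 0)
        dm <- tm$recon + (if (control$learn_b) tm$lognorm else 0)
        dtv_extra[k] <- (dp - dm) / (2 * h)
      }

      kl <- kl_gaussian(fw$mu, sig^2, lam2)
      dmu <- deta + klw * fw$mu / lam2
      dlv <- deta * sig * z / 2 + klw * 0.5 * (sig^2 / lam2 - 1)
      genc <- .encsun_backward(enc, fw$cache, dmu, dlv)

      g <- list(enc = genc, log_tv = params$log_tv * 0)
      g$log_tv[K[K %in% popset$learned]] <-
        deta[K[K %in% popset$learned]]
      g$log_tv[extra_tv] <- dtv_extra
      if (control$learn_b)
        g$log_b <- -2 * base$recon +
          length(p$observations$value) * 1  # d lognorm / d log b
      grad_sum <- if (is.null(grad_sum)) g else .par_add(grad_sum, g)
      tot <- tot + data0 + klw * sum(kl)
      rec <- rec + base$recon
      klt <- klt + klw * sum(kl)
    }
    ntr <- length(tr_ids)
    grads <- .par_scale(grad_sum, 1 / ntr)
    grads <- .clip_grads(grads, control$clip)
    total <- tot / ntr
    if (!is.finite(total))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    stp <- .adam_step(params, grads, opt, lr = control$lr)
    params <- stp$params; opt <- stp$state
    if (control$weight_decay > 0)
      params$enc <- .par_scale(params$enc,
                               1 - control$lr * control$weight_decay)
    trace[epoch, 1:3] <- c(total, rec / ntr, klt / ntr)

    if (length(val_ids) > 0) {
      enc$params <- params$enc
      bb <- if (control$learn_b) exp(params$log_b) else control$b_init
      vl <- mean(vapply(seq_along(val_ids), function(j) {
        p <- pats[[val_ids[j]]]
        st <- .sun_static(p); sq <- .sun_seq(p)
        fw <- .encsun_forward(enc, st$x, st$mask, sq$time, sq$values)
        eta <- fw$mu + exp(fw$log_var / 2) * z_val[j, ]
        names(eta) <- K
        dt <- patient_terms(p, params, eta, bb)
        dt$recon + (if (control$learn_b) dt$lognorm else 0) +
          sum(kl_gaussian(fw$mu, exp(fw$log_var), lam2))
      }, numeric(1)))
      trace[epoch, 4] <- vl
      if (vl < best$loss - 1e-8) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
    if (control$verbose && epoch %% 10 == 0)
      message(sprintf("epoch %d: loss %.4f", epoch, total))
  }
  if (length(val_ids) > 0 && best$epoch > 0L) params <- best$params

  enc$params <- params$enc
  popset$tv[popset$learned] <- exp(params$log_tv)
  if (control$learn_b) popset$error_b <- exp(params$log_b)
  trace <- as.data.frame(trace[!is.na(trace[, 1L]), , drop = FALSE])
  trace$epoch <- seq_len(nrow(trace))
  list(drug_type = "sunitinib", encoder = enc, popset = popset,
       control = control, loss = .final_decomposition(trace),
       trace = trace, val_patient_ids = sort(val_ids),
       n_samples = sum(data$events$EVT == "obs"))
}
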