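# S3 methods for fitted models: posterior-mean prediction (the expected
# value of the individual profile), typical-value prediction, posterior /
# prior simulation of replicate datasets, residuals and basic displays.

#' @export
print.vampk <- function(x, ...) {
  cat("Variational amortized mixed-effects PK model (",
      x$drug_type, ")\n", sep = "")
  cat("  observations:", x$n_samples,
      "| epochs run:", nrow(x$trace), "\n")
  learned <- x$popset$learned
  cat("  typical values (learned):\n")
  for (k in learned)
    cat(sprintf("    TV_%-4s = %.4g\n", k, x$popset$tv[[k]]))
  fixed <- setdiff(names(x$popset$tv), learned)
  if (length(fixed) > 0)
    cat("  fixed:", paste(sprintf("%s=%.4g", fixed, x$popset$tv[fixed]),
                          collapse = ", "), "\n")
  cat(sprintf("  residual b = %.4g | prior lambda = %.4g\n",
              x$popset$error_b, x$popset$lambda))
  cat(sprintf("  final loss %.4f (reconstruction %.4f, KL %.4f)\n",
              x$loss$total, x$loss$reconstruction, x$loss$kl))
  invisible(x)
}

#' @export
coef.vampk <- function(object, ...) {
  c(object$popset$tv, b = object$popset$error_b)
}

#' @export
summary.vampk <- function(object, ...) {
  eta <- posterior_eta(object, object$data)
  out <- list(fit = object, eta = eta)
  class(out) <- "summary.vampk"
  out
}

#' @export
print.summary.vampk <- function(x, ...) {
  print(x$fit)
  mu_cols <- grep("^mu_", names(x$eta), value = TRUE)
  cat("  training-set posterior-mean random effects:\n")
  for (cl in mu_cols)
    cat(sprintf("    %s: mean %.3f, sd %.3f\n", sub("^mu_", "eta_", cl),
                mean(x$eta[[cl]]), stats::sd(x$eta[[cl]])))
  invisible(x)
}

#' Per-patient posterior statistics of the random effects
#'
#' For the steady-state intravenous design the encoder emits one posterior
#' per measurement sample; the patient-level posterior mean is the average
#' of the sample-level means (variances are averaged likewise). For the
#' oral design the encoder is per patient already.
#'
#' @param object a fitted [vampk()] model.
#' @param data a [pk_dataset()] (defaults to the training data).
#' @param level `"patient"` (default) or `"sample"` (intravenous design
#'   only).
#' @return Data frame with `patient_id` and columns `mu_<k>` / `var_<k>`
#'   for every IIV parameter k.
#' @export
posterior_eta <- function(object, data = object$data,
                          level = c("patient", "sample")) {
  stopifnot(inherits(object, "vampk"))
  level <- match.arg(level)
  K <- object$popset$iiv
  if (object$drug_type == "fu5") {
    sm <- .fu5_samples(data)
    fw <- .enc5_forward(object$encoder, sm$X, sm$mask)
    df <- data.frame(patient_id = sm$patient_id,
                     mu = fw$mu[, 1L], var = exp(fw$log_var[, 1L]))
    if (level == "sample") {
      names(df) <- c("patient_id", paste0("mu_", K), paste0("var_", K))
      return(df)
    }
    agg <- stats::aggregate(cbind(mu, var) ~ patient_id, df, mean)
    names(agg) <- c("patient_id", paste0("mu_", K), paste0("var_", K))
    agg[match(unique(sm$patient_id), agg$patient_id), , drop = FALSE]
  } else {
    pats <- pk_patients(data)
    rows <- lapply(pats, function(p) {
      st <- .sun_static(p); sq <- .sun_seq(p)
      fw <- .encsun_forward(object$encoder, st$x, st$mask, sq$time,
                            sq$values)
      c(fw$mu, exp(fw$log_var))
    })
    m <- do.call(rbind, rows)
    colnames(m) <- c(paste0("mu_", K), paste0("var_", K))
    data.frame(patient_id = names(pats), m, row.names = NULL)
  }
}

#' Predict concentrations for patients
#'
#' `type = "posterior"` (the individual prediction protocol): random
#' effects set to the posterior means emitted by the encoder — the
#' expected value of the posterior — with no sampling and no residual
#' error. `type = "typical"` sets all random effects to zero (the typical
#' population prediction used for prediction correction in visual
#' predictive checks).
#'
#' For the intravenous design each measurement is its own encoder sample;
#' `encoding = "loo"` replaces each sample's posterior mean with the
#' average over the patient's *other* samples (honest prediction for a
#' measurement the encoder has not seen), falling back to the own sample
#' for singletons.
#'
#' @param object a fitted [vampk()] model.
#' @param newdata a [pk_dataset()]; defaults to the training data.
#' @param type `"posterior"` or `"typical"`.
#' @param encoding `"self"` (default; the paper's per-measurement design)
#'   or `"loo"`.
#' @param ... unused.
#' @return Data frame `patient_id, time, analyte, observed, predicted`.
#' @export
predict.vampk <- function(object, newdata = object$data,
                          type = c("posterior", "typical"),
                          encoding = c("self", "loo"), ...) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  K <- object$popset$iiv
  tv <- object$popset$tv
  if (object$drug_type == "fu5") {
    sm <- .fu5_samples(newdata)
    if (type == "typical") {
      eta <- rep(0, length(sm$y))
    } else {
      fw <- .enc5_forward(object$encoder, sm$X, sm$mask)
      eta <- fw$mu[, 1L]
      if (encoding == "loo") {
        for (id in unique(sm$patient_id)) {
          j <- which(sm$patient_id == id)
          if (length(j) > 1L)
            for (i in j) eta[i] <- mean(fw$mu[setdiff(j, i), 1L])
        }
      }
    }
    pred <- css_5fu(sm$D, sm$IT, tv[["CL"]] * exp(eta))
    data.frame(patient_id = sm$patient_id, time = sm$time,
               analyte = "parent", observed = sm$y, predicted = pred,
               row.names = NULL)
  } else {
    pats <- pk_patients(newdata)
    spec <- structural_model("sunitinib")
    out <- lapply(pats, function(p) {
      if (type == "typical") {
        eta <- stats::setNames(rep(0, length(K)), K)
      } else {
        st <- .sun_static(p); sq <- .sun_seq(p)
        fw <- .encsun_forward(object$encoder, st$x, st$mask, sq$time,
                              sq$values)
        eta <- stats::setNames(fw$mu, K)
      }
      theta <- allometric_scale(individual_params(object$popset, eta),
                                p$covariates[["WT"]])
      obs <- p$observations
      times <- sort(unique(obs$time))
      prof <- solve_profile(spec, theta, p$doses, times,
                            object$control$rtol, object$control$atol)
      yhat <- prof[cbind(match(obs$time, times),
                         match(obs$analyte, colnames(prof)))]
      data.frame(patient_id = p$patient_id, time = obs$time,
                 analyte = obs$analyte, observed = obs$value,
                 predicted = yhat, row.names = NULL)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
}

#' Simulate replicate concentration sets
#'
#' Draws `nsim` replicates of every observation in `newdata`.
#' `mode = "posterior"` samples the random effects from each unit's
#' encoder posterior; `mode = "prior"` samples them from the population
#' prior N(0, lambda^2), once per patient per replicate. Proportional
#' residual error (coefficient `b`) is multiplied in when
#' `with_residual = TRUE`.
#'
#' @param object a fitted [vampk()] model.
#' @param nsim number of replicates.
#' @param seed integer seed (mandatory).
#' @param newdata a [pk_dataset()]; defaults to the training data.
#' @param mode `"posterior"` or `"prior"`.
#' @param with_residual multiply in proportional residual noise.
#' @param ... unused.
#' @return Numeric matrix, rows aligned with `predict(object, newdata)`,
#'   one column per replicate.
#' @export
simulate.vampk <- function(object, nsim = 1, seed, newdata = object$data,
                           mode = c("posterior", "prior"),
                           with_residual = FALSE, ...) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  K <- object$popset$iiv
  tv <- object$popset$tv
  lam <- object$popset$lambda
  b <- object$popset$error_b
  if (object$drug_type == "fu5") {
    sm <- .fu5_samples(newdata)
    n <- length(sm$y)
    fw <- .enc5_forward(object$encoder, sm$X, sm$mask)
    out <- matrix(NA_real_, n, nsim)
    pid <- sm$patient_id
    upid <- unique(pid)
    for (r in seq_len(nsim)) {
      eta <- if (mode == "posterior")
        stats::rnorm(n, fw$mu[, 1L], exp(fw$log_var[, 1L] / 2))
      else
        stats::rnorm(length(upid), 0, lam)[match(pid, upid)]
      y <- css_5fu(sm$D, sm$IT, tv[["CL"]] * exp(eta))
      if (with_residual) y <- y * (1 + b * stats::rnorm(n))
      out[, r] <- y
    }
    out
  } else {
    pats <- pk_patients(newdata)
    spec <- structural_model("sunitinib")
    post <- lapply(pats, function(p) {
      st <- .sun_static(p); sq <- .sun_seq(p)
      .encsun_forward(object$encoder, st$x, st$mask, sq$time, sq$values)
    })
    n_obs <- vapply(pats, function(p) nrow(p$observations), integer(1))
    out <- matrix(NA_real_, sum(n_obs), nsim)
    for (r in seq_len(nsim)) {
      row0 <- 0L
      for (i in seq_along(pats)) {
        p <- pats[[i]]
        eta <- if (mode == "posterior")
          stats::rnorm(length(K), post[[i]]$mu,
                       exp(post[[i]]$log_var / 2))
        else stats::rnorm(length(K), 0, lam)
        names(eta) <- K
        theta <- allometric_scale(individual_params(object$popset, eta),
                                  p$covariates[["WT"]])
        obs <- p$observations
        times <- sort(unique(obs$time))
        prof <- solve_profile(spec, theta, p$doses, times,
                              object$control$rtol, object$control$atol)
        y <- prof[cbind(match(obs$time, times),
                        match(obs$analyte, colnames(prof)))]
        if (with_residual) y <- y * (1 + b * stats::rnorm(length(y)))
        out[row0 + seq_along(y), r] <- y
        row0 <- row0 + length(y)
      }
    }
    out
  }
}

#' @export
residuals.vampk <- function(object, newdata = object$data, ...) {
  pr <- predict(object, newdata)
  pr$observed - pr$predicted
}

#' Goodness-of-fit scatter of a fitted model
#'
#' Posterior-mean predicted versus observed concentrations with the
#' identity line.
#'
#' @param x a fitted [vampk()] model.
#' @param newdata a [pk_dataset()]; defaults to the training data.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vampk <- function(x, newdata = x$data, ...) {
  pr <- predict(x, newdata)
  lim <- range(c(pr$observed, pr$predicted))
  graphics::plot(pr$predicted, pr$observed, xlim = lim, ylim = lim,
                 xlab = "predicted concentration",
                 ylab = "observed concentration", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pr)
}
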