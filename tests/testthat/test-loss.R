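test_that("Gaussian KL closed form matches Monte-Carlo estimates", {
  # oracle: KL = E_q[log q(eta) - log p(eta)] estimated from 1e6 draws
  triples <- list(c(0, 1, 1), c(1, 1, 1), c(0, 1, 4),
                  c(-0.5, 0.25, 1), c(0.3, 2, 0.5), c(2, 0.1, 1))
  set.seed(101)
  n <- 1e6
  for (tr in triples) {
    mu <- tr[1]; s2 <- tr[2]; l2 <- tr[3]
    x <- rnorm(n, mu, sqrt(s2))
    lq <- dnorm(x, mu, sqrt(s2), log = TRUE)
    lp <- dnorm(x, 0, sqrt(l2), log = TRUE)
    est <- mean(lq - lp)
    se <- sd(lq - lp) / sqrt(n)
    expect_lt(abs(kl_gaussian(mu, s2, l2) - est), 3 * se + 1e-12)
  }
  expect_equal(kl_gaussian(0, 1, 1), 0)
  expect_equal(kl_gaussian(1, 1, 1), 0.5)
  expect_equal(kl_gaussian(0, 1, 4), 0.5 * (0.25 - 1 + log(4)))
  expect_true(all(kl_gaussian(rnorm(50), exp(rnorm(50)), 1) >= 0))
  expect_error(kl_gaussian(0, -1, 1), "positive")
})

test_that("reconstruction term follows the proportional error model", {
  cfg <- loss_config(b = 0.2, learn_b = FALSE)
  expect_equal(reconstruction_nll(c(1, 2, 3), c(1, 2, 3), cfg), 0)
  expect_equal(reconstruction_nll(1.2, 1, cfg), 0.2^2 / (2 * 0.04))
  # scale invariance under prediction-proportional error
  y <- c(0.5, 0.9); yh <- c(0.6, 0.8)
  expect_equal(reconstruction_nll(2 * y, 2 * yh, cfg),
               reconstruction_nll(y, yh, cfg))
  expect_error(reconstruction_nll(1, -1, cfg), "positive")
  # literal observation-proportional variant
  cfg2 <- loss_config(b = 0.2, error_model = "prop_to_obs",
                      learn_b = FALSE)
  expect_equal(reconstruction_nll(1.2, 1, cfg2),
               0.04 / (2 * 0.04 * 1.2))
})

test_that("negative ELBO matches an independently coded loop (steady state)", {
  ds <- toy_fu5_dataset()
  set.seed(21)
  norm <- list(mean = rep(0, 9), sd = rep(1, 9))
  enc <- vampk:::.encoder_init("fu5", "CL",
                               encoder_config(hidden_static = c(8, 8),
                                              dropout = 0), norm)
  pop <- default_popset("fu5")
  cfg <- loss_config(lambda = 1.3, b = 0.25, learn_b = FALSE)
  got <- elbo_loss(ds, enc, pop, cfg, seed = 77)

  # brute force: walk the observations in event order, one at a time
  ev <- ds$events
  obs_rows <- which(ev$EVT == "obs")
  set.seed(77)
  z <- rnorm(length(obs_rows))
  acc_recon <- acc_kl <- numeric(0)
  for (j in seq_along(obs_rows)) {
    r <- obs_rows[j]
    dose_row <- max(which(ev$EVT == "dose" & ev$ID == ev$ID[r] &
                            ev$TIME <= ev$TIME[r]))
    feat <- matrix(c(ev$DV[r], ev$AMT[dose_row], ev$WT[r], ev$LBM[r],
                     ev$FM[r], ev$BSA[r], ev$AGE[r], ev$SEX[r], ev$HT[r]),
                   1, 9)
    ps <- encode_5fu(enc, feat)
    sig <- sqrt(exp(ps$log_var[1, 1]))
    eta <- ps$mu[1, 1] + sig * z[j]
    cl <- pop$tv[["CL"]] * exp(eta)
    yhat <- ev$AMT[dose_row] / (ev$DUR[dose_row] * cl)
    acc_recon[j] <- (ev$DV[r] - yhat)^2 / (2 * 0.25^2 * yhat^2)
    acc_kl[j] <- 0.5 * (sig^2 / 1.3^2 + ps$mu[1, 1]^2 / 1.3^2 - 1 +
                          log(1.3^2 / sig^2))
  }
  expect_equal(got$total, mean(acc_recon + acc_kl), tolerance = 1e-10)
  expect_equal(got$reconstruction, mean(acc_recon), tolerance = 1e-10)
  expect_equal(got$kl, mean(acc_kl), tolerance = 1e-10)
})

test_that("negative ELBO matches an independently coded loop (oral design)", {
  cfgc <- cohort_config_sunitinib(n_patients = 3, n_cycles = 1,
                                  samples_prob = c(0, 1, 1, rep(0, 11)) / 2)
  coh <- generate_sunitinib_cohort(cfgc, seed = 31)
  ds <- coh$dataset
  set.seed(22)
  pats0 <- pk_patients(ds)
  Xs <- do.call(rbind, lapply(pats0, function(p) vampk:::.sun_static(p)$x))
  Ms <- do.call(rbind, lapply(pats0,
                              function(p) vampk:::.sun_static(p)$mask))
  sq_all <- do.call(rbind, lapply(pats0,
                                  function(p) vampk:::.sun_seq(p)$values))
  norm <- list(static = vampk:::.norm_stats(Xs, Ms),
               seq = vampk:::.norm_stats(vampk:::.seq_log(sq_all),
                                         matrix(1, nrow(sq_all), 2)))
  K <- c("CLS", "V2S", "FM", "V2M")
  enc <- vampk:::.encoder_init("sunitinib", K,
                               encoder_config(hidden_static = c(8, 8),
                                              hidden_recurrent = 6,
                                              hidden_projection = 8,
                                              dropout = 0), norm)
  pop <- default_popset("sunitinib")
  cfg <- loss_config(lambda = 1, b = 0.3, learn_b = FALSE)
  got <- elbo_loss(ds, enc, pop, cfg, seed = 55)

  spec <- structural_model("sunitinib")
  pats <- pk_patients(ds)
  set.seed(55)
  per <- numeric(0)
  for (p in pats) {
    obs <- p$observations
    times <- sort(unique(obs$time))
    sq <- data.frame(
      time = times,
      parent = obs$value[obs$analyte == "parent"][match(times,
        obs$time[obs$analyte == "parent"])],
      metab = obs$value[obs$analyte == "metab"][match(times,
        obs$time[obs$analyte == "metab"])])
    ps <- encode_sunitinib(enc, p$covariates, sq)
    z <- rnorm(4)
    eta <- ps$mu + sqrt(exp(ps$log_var)) * z
    th <- pop$tv
    th[K] <- th[K] * exp(eta[K])
    th <- allometric_scale(th, p$covariates[["WT"]])
    prof <- solve_profile(spec, th, p$doses, times,
                          rtol = 1e-6, atol = 1e-8)
    yhat <- ifelse(obs$analyte == "parent",
                   prof[match(obs$time, times), "parent"],
                   prof[match(obs$time, times), "metab"])
    recon <- sum((obs$value - yhat)^2 / (2 * 0.3^2 * yhat^2))
    kl <- sum(0.5 * (exp(ps$log_var) + ps$mu^2 - 1 - ps$log_var))
    per <- c(per, recon + kl)
  }
  expect_equal(got$total, mean(per), tolerance = 1e-10)
})

test_that("loss decomposition is exact and KL weight 0 isolates the data term", {
  ds <- toy_fu5_dataset()
  set.seed(23)
  enc <- vampk:::.encoder_init("fu5", "CL",
                               encoder_config(hidden_static = c(8, 8),
                                              dropout = 0),
                               list(mean = rep(0, 9), sd = rep(1, 9)))
  pop <- default_popset("fu5")
  l1 <- elbo_loss(ds, enc, pop, loss_config(learn_b = FALSE), seed = 5)
  expect_equal(l1$total, l1$reconstruction + l1$kl, tolerance = 1e-8)
  l0 <- elbo_loss(ds, enc, pop,
                  loss_config(kl_weight = 0, learn_b = FALSE), seed = 5)
  expect_equal(l0$total, l0$reconstruction)
  # with a learned b the Gaussian normalizer joins the decomposition
  lb <- elbo_loss(ds, enc, pop, loss_config(learn_b = TRUE), seed = 5)
  expect_equal(lb$total, lb$reconstruction + lb$kl + lb$lognorm,
               tolerance = 1e-8)
})
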