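# Amortized-inference encoders: neural networks mapping one patient's data
# to the mean and log-variance of a diagonal Gaussian posterior over the
# random effects eta_k, k in K.
#
# Missing covariates use mask concatenation: each input block is the
# standardized feature vector with missing slots zeroed, concatenated with
# its binary observed-mask, so the network can distinguish "value 0" from
# "value unknown" and the output is invariant to whatever sits in a
# masked-out slot.

.enc5_features <- c("CONC", "DOSE", "WT", "LBM", "FM", "BSA", "AGE",
                    "SEX", "HT")
.encsun_static <- c("SEX", "AGE", "WT", "HT", "BSA", "LBM", "FM")

#' Encoder configuration
#'
#' Architecture hyperparameters for the amortized-inference encoders.
#' Widths are numbers of units; `dropout` is the drop probability applied
#' to hidden activations during training only.
#'
#' @param hidden_static widths of the static-covariate block.
#' @param hidden_recurrent hidden width of the time-gated recurrent block
#'   (sunitinib only).
#' @param hidden_projection hidden width of each posterior head.
#' @param dropout dropout rate in (0, 1), training mode only.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(hidden_static = c(32, 32),
                           hidden_recurrent = 32,
                           hidden_projection = 32,
                           dropout = 0.1) {
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(hidden_static = hidden_static,
                 hidden_recurrent = hidden_recurrent,
                 hidden_projection = hidden_projection,
                 dropout = dropout),
            class = "encoder_config")
}

# standardization statistics from TRAINING data only; masked entries do not
# contribute. Returned sds have a floor so constant features stay finite.
.norm_stats <- function(X, mask) {
  mu <- numeric(ncol(X)); sd_ <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[mask[, j] > 0, j]
    mu[j] <- if (length(v) > 0) mean(v) else 0
    s <- if (length(v) > 1) stats::sd(v) else 1
    sd_[j] <- if (is.finite(s) && s > 1e-8) s else 1
  }
  list(mean = mu, sd = sd_)
}

# concentration sequences are log-normal; encode on the log scale
# (nonpositive / absent values map to 0)
.seq_log <- function(v) ifelse(v > 0, log(v), 0)

.apply_norm <- function(X, mask, norm) {
  Xn <- sweep(sweep(X, 2L, norm$mean, `-`), 2L, norm$sd, `/`)
  Xn[mask == 0] <- 0
  cbind(Xn * mask, mask)
}

## ---- construction --------------------------------------------------------

# norm statistics must come from the training fold (see .norm_stats)
.encoder_init <- function(drug_type, K, config, norm) {
  if (drug_type == "fu5") {
    d_in <- 2 * length(.enc5_features)
    params <- list(
      trunk = .mlp_init(c(d_in, config$hidden_static)),
      mu = .mlp_init(c(utils::tail(config$hidden_static, 1L), length(K))),
      lv = .mlp_init(c(utils::tail(config$hidden_static, 1L), length(K))),
      # linear skip from the (standardized) input to each head: the
      # posterior-mean map is near-linear in the log inputs, and the skip
      # keeps extrapolation linear outside the training range
      skip_mu = matrix(0, d_in, length(K)),
      skip_lv = matrix(0, d_in, length(K)))
  } else {
    d_static <- 2 * length(.encsun_static)
    h_s <- utils::tail(config$hidden_static, 1L)
    h_r <- config$hidden_recurrent
    d_proj <- h_s + h_r
    params <- list(
      static = .mlp_init(c(d_static, config$hidden_static)),
      cell = .tlstm_init(3L, h_r),
      mu = .mlp_init(c(d_proj, config$hidden_projection, length(K))),
      lv = .mlp_init(c(d_proj, config$hidden_projection, length(K))))
  }
  structure(list(drug_type = drug_type, K = K, config = config,
                 params = params, norm = norm),
            class = "vampk_encoder")
}

## ---- 5FU path ------------------------------------------------------------

# concentration and dose are log-normal quantities; the encoder works on
# their log scale (before standardization)
.enc5_log <- function(X, mask) {
  for (j in 1:2)
    X[, j] <- ifelse(mask[, j] > 0, log(pmax(X[, j], 1e-12)), 0)
  X
}

# Each steady-state measurement is its own sample: features are the
# measured concentration (log), dose (log), and the static covariates.
# X raw n x 9, mask n x 9 (1 = observed). Returns mu/log_var (n x |K|).
.enc5_forward <- function(enc, X, mask, training = FALSE) {
  Xin <- .apply_norm(.enc5_log(X, mask), mask, enc$norm)
  p <- enc$params
  drop <- if (training) enc$config$dropout else 0
  tf <- .mlp_forward_do(p$trunk, Xin, drop)
  Hpre <- tf$out
  H <- .silu(Hpre)
  mu <- sweep(H %*% p$mu$W[[1L]] + Xin %*% p$skip_mu, 2L,
              p$mu$b[[1L]], `+`)
  lv <- sweep(H %*% p$lv$W[[1L]] + Xin %*% p$skip_lv, 2L,
              p$lv$b[[1L]], `+`)
  list(mu = mu, log_var = lv,
       cache = list(tf = tf, Hpre = Hpre, H = H, Xin = Xin))
}

.enc5_backward <- function(enc, cache, dmu, dlv) {
  p <- enc$params
  g_mu <- list(W = list(crossprod(cache$H, dmu)), b = list(colSums(dmu)))
  g_lv <- list(W = list(crossprod(cache$H, dlv)), b = list(colSums(dlv)))
  dH <- dmu %*% t(p$mu$W[[1L]]) + dlv %*% t(p$lv$W[[1L]])
  dHpre <- dH * .dsilu(cache$Hpre)
  bt <- .mlp_backward_do(p$trunk, cache$tf$cache, dHpre)
  list(trunk = bt$grads, mu = g_mu, lv = g_lv,
       skip_mu = crossprod(cache$Xin, dmu),
       skip_lv = crossprod(cache$Xin, dlv))
}

## ---- sunitinib path ------------------------------------------------------

# One patient: static covariates (+mask) through the static block; the
# (dt, parent, metabolite) sequence through the time-gated LSTM; the two
# representations concatenated into the projection heads.
.encsun_forward <- function(enc, static, static_mask, seq_times,
                            seq_values, training = FALSE) {
  if (length(seq_times) == 0L)
    stop("sunitinib encoder needs at least one observation", call. = FALSE)
  if (is.unsorted(seq_times))
    stop("observation sequence must be sorted by time", call. = FALSE)
  p <- enc$params
  drop <- if (training) enc$config$dropout else 0
  Xs <- .apply_norm(matrix(static, nrow = 1L),
                    matrix(static_mask, nrow = 1L), enc$norm$static)
  sf <- .mlp_forward_do(p$static, Xs, drop)
  Hs <- .silu(sf$out)
  dt <- c(0, diff(seq_times))
  Vn <- sweep(sweep(.seq_log(seq_values), 2L, enc$norm$seq$mean, `-`),
              2L, enc$norm$seq$sd, `/`)
  Xseq <- cbind(dt / 24, Vn)
  rf <- .tlstm_forward(p$cell, Xseq, dt)
  Hproj <- cbind(Hs, matrix(rf$h, nrow = 1L))
  mf <- .mlp_forward_do(p$mu, Hproj, drop)
  lf <- .mlp_forward_do(p$lv, Hproj, drop)
  list(mu = as.numeric(mf$out), log_var = as.numeric(lf$out),
       cache = list(sf = sf, Hs_pre = sf$out, rf = rf, Hproj = Hproj,
                    mf = mf, lf = lf, h_r = length(rf$h)))
}

.encsun_backward <- function(enc, cache, dmu, dlv) {
  p <- enc$params
  bm <- .mlp_backward_do(p$mu, cache$mf$cache, matrix(dmu, nrow = 1L))
  bl <- .mlp_backward_do(p$lv, cache$lf$cache, matrix(dlv, nrow = 1L))
  dHproj <- bm$dX + bl$dX
  h_s <- ncol(dHproj) - cache$h_r
  dHs <- dHproj[, seq_len(h_s), drop = FALSE]
  dh_final <- as.numeric(dHproj[, h_s + seq_len(cache$h_r)])
  bs <- .mlp_backward_do(p$static, cache$sf$cache, dHs * .dsilu(cache$Hs_pre))
  br <- .tlstm_backward(p$cell, cache$rf$cache, dh_final)
  list(static = bs$grads, cell = br$grads, mu = bm$grads, lv = bl$grads)
}

## ---- dropout-aware MLP wrappers ------------------------------------------

.mlp_forward_do <- function(net, X, dropout = 0) {
  if (dropout <= 0) {
    fw <- .mlp_forward(net, X)
    fw$cache$masks <- NULL
    return(fw)
  }
  L <- length(net$W)
  A <- list(X)
  Z <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    if (l < L) {
      act <- .silu(Z[[l]])
      m <- matrix(stats::rbinom(length(act), 1L, 1 - dropout) /
                    (1 - dropout), nrow(act), ncol(act))
      masks[[l]] <- m
      A[[l + 1L]] <- act * m
    } else {
      A[[l + 1L]] <- Z[[l]]
    }
  }
  list(out = A[[L + 1L]], cache = list(A = A, Z = Z, masks = masks))
}

.mlp_backward_do <- function(net, cache, dOut) {
  if (is.null(cache$masks)) return(.mlp_backward(net, cache, dOut))
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
    if (l > 1L)
      delta <- delta * cache$masks[[l - 1L]] * .dsilu(cache$Z[[l - 1L]])
  }
  list(grads = list(W = dW, b = db), dX = delta)
}

## ---- exported encoding operations ----------------------------------------

#' Encode steady-state measurement samples (intravenous design)
#'
#' Each measurement is its own sample: the encoder input is the
#' concatenation of the measured concentration, dose and static covariates
#' (weight, LBM, FM, BSA, age, sex, height) with its missing mask. Returns
#' the per-sample posterior mean and log-variance of eta (here |K| = 1,
#' the clearance random effect). Deterministic given the encoder weights.
#'
#' @param encoder a fitted or initialized encoder (from [vampk()] fits).
#' @param features numeric matrix, one row per measurement sample, columns
#'   `CONC, DOSE, WT, LBM, FM, BSA, AGE, SEX, HT`.
#' @param mask binary matrix of the same shape (1 = observed); defaults to
#'   all-observed.
#' @return A list with `mu` and `log_var`, matrices n x |K| with the IIV
#'   parameter names as columns.
#' @export
encode_5fu <- function(encoder, features, mask = NULL) {
  stopifnot(inherits(encoder, "vampk_encoder"),
            encoder$drug_type == "fu5")
  features <- as.matrix(features)
  if (ncol(features) != length(.enc5_features))
    stop("expected ", length(.enc5_features), " feature columns (",
         paste(.enc5_features, collapse = ", "), ")", call. = FALSE)
  if (is.null(mask)) mask <- (!is.na(features)) * 1
  features[is.na(features)] <- 0
  fw <- .enc5_forward(encoder, features, mask, training = FALSE)
  colnames(fw$mu) <- encoder$K
  colnames(fw$log_var) <- encoder$K
  list(mu = fw$mu, log_var = fw$log_var)
}

#' Encode one patient of the oral parent-metabolite design
#'
#' Static covariates pass through a feed-forward block; the irregularly
#' sampled (time, parent, metabolite) sequence passes through a time-gated
#' LSTM whose memory decay depends on the gap between observations; both
#' representations feed two projection heads producing |K| = 4 posterior
#' means and log-variances (CLS, V2S, FM, V2M random effects).
#'
#' @param encoder a sunitinib encoder.
#' @param static named covariate vector (`SEX, AGE, WT, HT, BSA, LBM, FM`),
#'   `NA` where missing.
#' @param sequence data frame with columns `time` (h, sorted), `parent`,
#'   `metab` (concentrations, ng/mL).
#' @return A list with named vectors `mu` and `log_var` over K.
#' @export
encode_sunitinib <- function(encoder, static, sequence) {
  stopifnot(inherits(encoder, "vampk_encoder"),
            encoder$drug_type == "sunitinib")
  static <- static[.encsun_static]
  mask <- as.numeric(!is.na(static))
  static[is.na(static)] <- 0
  vals <- as.matrix(sequence[, c("parent", "metab")])
  vals[is.na(vals)] <- 0
  fw <- .encsun_forward(encoder, as.numeric(static), mask,
                        sequence$time, vals, training = FALSE)
  mu <- fw$mu; log_var <- fw$log_var
  names(mu) <- encoder$K; names(log_var) <- encoder$K
  list(mu = mu, log_var = log_var)
}
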