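# Minimal neural-network toolkit used by the amortized-inference encoders:
# a fully connected net with a smooth nonsaturating activation (SiLU), a
# time-gated LSTM cell for irregularly sampled sequences, reverse-mode
# gradients for both, and an Adam optimizer over nested parameter lists.
# Everything is plain base R; gradients are verified against finite
# differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.silu <- function(x) x * .sigmoid(x)
.dsilu <- function(x) {
  s <- .sigmoid(x)
  s * (1 + x * (1 - s))
}
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## ---- nested parameter-list utilities -------------------------------------

.par_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1L]])) {
    out <- lapply(seq_along(args[[1L]]), function(i)
      do.call(.par_map, c(list(f), lapply(args, `[[`, i))))
    names(out) <- names(args[[1L]])
    out
  } else {
    do.call(f, args)
  }
}

.par_zeros <- function(p) .par_map(function(x) x * 0, p)

.par_sqsum <- function(p) {
  if (is.list(p)) sum(vapply(p, .par_sqsum, numeric(1))) else sum(p^2)
}

.par_scale <- function(p, s) .par_map(function(x) x * s, p)

.par_add <- function(a, b) .par_map(`+`, a, b)

# global gradient-norm clipping
.clip_grads <- function(g, max_norm) {
  nrm <- sqrt(.par_sqsum(g))
  if (is.finite(nrm) && nrm > max_norm) .par_scale(g, max_norm / nrm) else g
}

## ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .par_zeros(params), v = .par_zeros(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .par_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- .par_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .par_map(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

## ---- fully connected network ---------------------------------------------

# sizes: c(input, hidden..., output); hidden layers use SiLU, output linear
.mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(1 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# X: n x d matrix. Returns list(out, cache) where cache holds the
# pre-activations needed for the backward pass.
.mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- list(X)
  Z <- vector("list", L)
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) .silu(Z[[l]]) else Z[[l]]
  }
  list(out = A[[L + 1L]], cache = list(A = A, Z = Z))
}

# dOut: gradient of the loss w.r.t. the network output (n x out).
# Returns list(grads = list(W, b), dX).
.mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut  # gradient w.r.t. Z[[L]] (linear output layer)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
    if (l > 1L) delta <- delta * .dsilu(cache$Z[[l - 1L]])
  }
  list(grads = list(W = dW, b = db), dX = delta)
}

## ---- time-gated LSTM -----------------------------------------------------

# LSTM whose previous cell state is discounted by exp(-softplus(d) * dt/24)
# before the gate update: elapsed time between observations (dt, hours)
# modulates how much short-term memory survives. dt = 0 gives exactly the
# standard LSTM step.
.tlstm_init <- function(input_dim, hidden_dim) {
  sd_w <- sqrt(1 / input_dim)
  sd_u <- sqrt(1 / hidden_dim)
  list(
    W = matrix(stats::rnorm(input_dim * 4 * hidden_dim, sd = sd_w),
               input_dim, 4 * hidden_dim),
    U = matrix(stats::rnorm(hidden_dim * 4 * hidden_dim, sd = sd_u),
               hidden_dim, 4 * hidden_dim),
    b = c(rep(0, hidden_dim), rep(1, hidden_dim), rep(0, 2 * hidden_dim)),
    d = rep(-1, hidden_dim))  # softplus(-1) ~ 0.31 / day initial decay
}

.tlstm_gates <- function(hidden_dim) {
  list(i = seq_len(hidden_dim),
       f = hidden_dim + seq_len(hidden_dim),
       o = 2 * hidden_dim + seq_len(hidden_dim),
       g = 3 * hidden_dim + seq_len(hidden_dim))
}

#' One step of the time-gated recurrent cell
#'
#' Applies elapsed-time discounting `c <- c * exp(-softplus(d) * dt/24)` to
#' the previous cell state, then a standard LSTM gate update. With
#' `dt = 0` the discount is 1 and the step reduces to a plain LSTM step.
#'
#' @param cell cell parameter list (`W`, `U`, `b`, `d`).
#' @param x input vector for this step.
#' @param h_prev,c_prev previous hidden and cell state.
#' @param dt elapsed time since the previous observation (hours, >= 0).
#' @return List with `h` and `c`.
#' @export
time_recurrent_update <- function(cell, x, h_prev, c_prev, dt) {
  if (dt < 0) stop("elapsed time dt must be nonnegative", call. = FALSE)
  H <- length(h_prev)
  idx <- .tlstm_gates(H)
  decay <- exp(-.softplus(cell$d) * dt / 24)
  c_star <- c_prev * decay
  z <- as.numeric(x %*% cell$W + h_prev %*% cell$U) + cell$b
  i <- .sigmoid(z[idx$i]); f <- .sigmoid(z[idx$f])
  o <- .sigmoid(z[idx$o]); g <- tanh(z[idx$g])
  c_new <- f * c_star + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new)
}

# Full forward over one sequence. X: n_t x p, dt: length n_t (dt[1] is the
# gap from the sequence origin; use 0 for "no prior history").
.tlstm_forward <- function(cell, X, dt) {
  n_t <- nrow(X)
  H <- length(cell$d)
  idx <- .tlstm_gates(H)
  h <- rep(0, H); c_state <- rep(0, H)
  cache <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    decay <- exp(-.softplus(cell$d) * dt[t] / 24)
    c_star <- c_state * decay
    z <- as.numeric(X[t, ] %*% cell$W + h %*% cell$U) + cell$b
    i <- .sigmoid(z[idx$i]); f <- .sigmoid(z[idx$f])
    o <- .sigmoid(z[idx$o]); g <- tanh(z[idx$g])
    c_new <- f * c_star + i * g
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(x = X[t, ], dt = dt[t], h_prev = h,
                       c_prev = c_state, decay = decay, c_star = c_star,
                       i = i, f = f, o = o, g = g, c_new = c_new)
    h <- h_new; c_state <- c_new
  }
  list(h = h, c = c_state, cache = cache)
}

# BPTT through one sequence; dh_final is the loss gradient w.r.t. the final
# hidden state. Returns gradients for W, U, b, d and the input rows.
.tlstm_backward <- function(cell, cache, dh_final) {
  H <- length(cell$d)
  idx <- .tlstm_gates(H)
  n_t <- length(cache)
  dW <- cell$W * 0; dU <- cell$U * 0
  db <- cell$b * 0; dd <- cell$d * 0
  dX <- matrix(0, n_t, nrow(cell$W))
  dh <- dh_final
  dc <- rep(0, H)
  for (t in rev(seq_len(n_t))) {
    cc <- cache[[t]]
    tanh_c <- tanh(cc$c_new)
    do_ <- dh * tanh_c
    dc_total <- dc + dh * cc$o * (1 - tanh_c^2)
    df <- dc_total * cc$c_star
    di <- dc_total * cc$g
    dg <- dc_total * cc$i
    dc_star <- dc_total * cc$f
    # decay gate: c_star = c_prev * exp(-softplus(d) * dt/24)
    dd <- dd + dc_star * cc$c_prev * cc$decay *
      (-cc$dt / 24) * .sigmoid(cell$d)
    dc_prev <- dc_star * cc$decay
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            do_ * cc$o * (1 - cc$o),
            dg * (1 - cc$g^2))
    dW <- dW + outer(cc$x, dz)
    dU <- dU + outer(cc$h_prev, dz)
    db <- db + dz
    dX[t, ] <- as.numeric(cell$W %*% dz)
    dh <- as.numeric(cell$U %*% dz)
    dc <- dc_prev
  }
  list(grads = list(W = dW, U = dU, b = db, d = dd), dX = dX)
}
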