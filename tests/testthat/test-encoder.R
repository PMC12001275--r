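make_enc5 <- function(seed = 1) {
  set.seed(seed)
  norm <- list(mean = rep(0, 9), sd = rep(1, 9))
  vampk:::.encoder_init("fu5", "CL",
                        encoder_config(hidden_static = c(8, 8),
                                       dropout = 0),
                        norm)
}

make_encsun <- function(seed = 2, h = 6) {
  set.seed(seed)
  norm <- list(static = list(mean = rep(0, 7), sd = rep(1, 7)),
               seq = list(mean = rep(0, 2), sd = rep(1, 2)))
  vampk:::.encoder_init("sunitinib", c("CLS", "V2S", "FM", "V2M"),
                        encoder_config(hidden_static = c(8, 8),
                                       hidden_recurrent = h,
                                       hidden_projection = 8,
                                       dropout = 0),
                        norm)
}

test_that("steady-state encoder emits one posterior per measurement sample", {
  enc <- make_enc5()
  X <- matrix(abs(rnorm(27)) + 0.5, 3, 9,
              dimnames = list(NULL, vampk:::.enc5_features))
  out <- encode_5fu(enc, X)
  expect_identical(dim(out$mu), c(3L, 1L))
  expect_identical(colnames(out$mu), "CL")
  expect_identical(dim(out$log_var), c(3L, 1L))
  # variances strictly positive by construction
  expect_true(all(exp(out$log_var) > 0))
  # determinism in eval mode
  expect_identical(out, encode_5fu(enc, X))
  expect_error(encode_5fu(enc, X[, 1:5]), "feature")
})

test_that("masked-out covariate slots cannot influence the encoding", {
  enc <- make_enc5()
  set.seed(9)
  for (i in 1:10) {
    X <- matrix(abs(rnorm(9)) + 0.5, 1, 9)
    mask <- matrix(c(1, 1, rbinom(7, 1, 0.6)), 1, 9)  # conc/dose observed
    out1 <- encode_5fu(enc, X, mask)
    X2 <- X
    off <- which(mask == 0)
    if (length(off) == 0) next
    X2[off] <- X2[off] + rnorm(length(off), sd = 10)
    out2 <- encode_5fu(enc, X2, mask)
    expect_identical(out1, out2)
  }
})

test_that("sequence encoder produces 4 + 4 outputs for any history length", {
  enc <- make_encsun()
  static <- c(SEX = 1, AGE = 60, WT = 75, HT = 175, BSA = 1.9,
              LBM = 55, FM = 20)
  one <- data.frame(time = 23.5, parent = 40, metab = 12)
  out1 <- encode_sunitinib(enc, static, one)
  expect_length(out1$mu, 4L)
  expect_length(out1$log_var, 4L)
  expect_identical(names(out1$mu), c("CLS", "V2S", "FM", "V2M"))
  many <- data.frame(time = c(23.5, 47.5, 167.5), parent = c(40, 55, 60),
                     metab = c(12, 18, 20))
  out2 <- encode_sunitinib(enc, static, many)
  expect_true(all(is.finite(out2$mu)))
  # a missing static covariate is handled through the mask
  static_na <- static; static_na["WT"] <- NA
  expect_true(all(is.finite(encode_sunitinib(enc, static_na, many)$mu)))
  expect_error(encode_sunitinib(enc, static, many[3:1, ]), "sorted")
})

test_that("inter-observation gaps modulate the recurrent encoding", {
  enc <- make_encsun()
  static <- c(SEX = 0, AGE = 55, WT = 68, HT = 162, BSA = 1.7,
              LBM = 45, FM = 23)
  vals <- data.frame(parent = c(40, 55), metab = c(12, 18))
  tight <- cbind(time = c(23.5, 47.5), vals)
  loose <- cbind(time = c(23.5, 335.5), vals)
  o1 <- encode_sunitinib(enc, static, tight)
  o2 <- encode_sunitinib(enc, static, loose)
  expect_gt(max(abs(o1$mu - o2$mu)), 1e-8)
})

test_that("zero elapsed time reduces the time gate to a plain LSTM step", {
  cell <- vampk:::.tlstm_init(3L, 5L)
  set.seed(3)
  x <- rnorm(3); h0 <- tanh(rnorm(5)); c0 <- rnorm(5)
  out <- time_recurrent_update(cell, x, h0, c0, dt = 0)
  # independent plain-LSTM computation of the same step
  z <- as.numeric(x %*% cell$W + h0 %*% cell$U) + cell$b
  sig <- function(u) 1 / (1 + exp(-u))
  i <- sig(z[1:5]); f <- sig(z[6:10]); o <- sig(z[11:15]); g <- tanh(z[16:20])
  c_ref <- f * c0 + i * g
  expect_equal(out$c, c_ref, tolerance = 1e-12)
  expect_equal(out$h, o * tanh(c_ref), tolerance = 1e-12)
  # hidden state bounded by the saturating output nonlinearity
  expect_true(all(abs(out$h) < 1))
  expect_error(time_recurrent_update(cell, x, h0, c0, dt = -1),
               "nonnegative")
})

test_that("analytic encoder gradients match finite differences", {
  enc <- make_enc5()
  set.seed(5)
  X <- matrix(abs(rnorm(4 * 9)) + 0.5, 4, 9)
  mask <- matrix(1, 4, 9)
  a <- matrix(rnorm(4), 4, 1); b2 <- matrix(rnorm(4), 4, 1)
  loss_of <- function(params) {
    e <- enc; e$params <- params
    fw <- vampk:::.enc5_forward(e, X, mask)
    sum(fw$mu * a) + sum(fw$log_var * b2)
  }
  fw <- vampk:::.enc5_forward(enc, X, mask)
  g <- vampk:::.enc5_backward(enc, fw$cache, a, b2)
  # spot-check several coordinates in every parameter block
  blocks <- list(
    c("trunk", "W", 1L), c("trunk", "b", 2L), c("mu", "W", 1L),
    c("lv", "b", 1L), c("skip_mu", NA, NA), c("skip_lv", NA, NA))
  for (bl in blocks) {
    get_block <- function(p) if (is.na(bl[2])) p[[bl[1]]]
                             else p[[bl[1]]][[bl[2]]][[as.integer(bl[3])]]
    ref <- get_block(enc$params)
    idx <- sample(length(ref), min(4, length(ref)))
    for (j in idx) {
      fd <- (function(eps) {
        pp <- enc$params; pm <- enc$params
        if (is.na(bl[2])) {
          pp[[bl[1]]][j] <- pp[[bl[1]]][j] + eps
          pm[[bl[1]]][j] <- pm[[bl[1]]][j] - eps
        } else {
          pp[[bl[1]]][[bl[2]]][[as.integer(bl[3])]][j] <-
            pp[[bl[1]]][[bl[2]]][[as.integer(bl[3])]][j] + eps
          pm[[bl[1]]][[bl[2]]][[as.integer(bl[3])]][j] <-
            pm[[bl[1]]][[bl[2]]][[as.integer(bl[3])]][j] - eps
        }
        (loss_of(pp) - loss_of(pm)) / (2 * eps)
      })(1e-5)
      expect_equal(get_block(g)[j], fd, tolerance = 1e-5)
    }
  }
})

test_that("backpropagation through time matches finite differences", {
  cell <- vampk:::.tlstm_init(2L, 4L)
  set.seed(6)
  X <- matrix(rnorm(6), 3, 2)
  dt <- c(0, 24, 96)
  w <- rnorm(4)
  loss_of <- function(cl) sum(vampk:::.tlstm_forward(cl, X, dt)$h * w)
  fw <- vampk:::.tlstm_forward(cell, X, dt)
  bk <- vampk:::.tlstm_backward(cell, fw$cache, w)
  for (nm in c("W", "U", "b", "d")) {
    ref <- cell[[nm]]
    idx <- sample(length(ref), min(5, length(ref)))
    for (j in idx) {
      cp <- cell; cp[[nm]][j] <- cp[[nm]][j] + 1e-5
      cm <- cell; cm[[nm]][j] <- cm[[nm]][j] - 1e-5
      fd <- (loss_of(cp) - loss_of(cm)) / 2e-5
      expect_equal(bk$grads[[nm]][j], fd, tolerance = 1e-5)
    }
  }
})

test_that("gradient reaches every trainable block of both encoders", {
  enc <- make_enc5()
  set.seed(8)
  X <- matrix(abs(rnorm(6 * 9)) + 0.5, 6, 9)
  fw <- vampk:::.enc5_forward(enc, X, matrix(1, 6, 9))
  g <- vampk:::.enc5_backward(enc, fw$cache,
                              matrix(rnorm(6), 6, 1),
                              matrix(rnorm(6), 6, 1))
  expect_gt(sqrt(vampk:::.par_sqsum(g$trunk)), 0)
  expect_gt(sqrt(vampk:::.par_sqsum(g$mu)), 0)
  expect_gt(sqrt(vampk:::.par_sqsum(g$lv)), 0)
  expect_gt(sum(g$skip_mu^2), 0)

  encs <- make_encsun()
  fws <- vampk:::.encsun_forward(encs, rnorm(7), rep(1, 7),
                                 c(23.5, 47.5),
                                 matrix(abs(rnorm(4)) + 1, 2, 2))
  gs <- vampk:::.encsun_backward(encs, fws$cache, rnorm(4), rnorm(4))
  for (block in c("static", "cell", "mu", "lv")) {
    nrm <- sqrt(vampk:::.par_sqsum(gs[[block]]))
    expect_true(is.finite(nrm))
    expect_gt(nrm, 0)
  }
})

test_that("normalization statistics come from training data alone", {
  X <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  mask <- matrix(1, 3, 2)
  ns <- vampk:::.norm_stats(X, mask)
  expect_equal(ns$mean, c(2, 20))
  expect_equal(ns$sd, c(1, 10))
  # masked entries do not contribute
  mask2 <- mask; mask2[3, 1] <- 0
  ns2 <- vampk:::.norm_stats(X, mask2)
  expect_equal(ns2$mean[1], 1.5)
  # applying the stats to new data leaves them untouched (pure function)
  before <- ns
  invisible(vampk:::.apply_norm(matrix(100, 1, 2), matrix(1, 1, 2), ns))
  expect_identical(ns, before)
})
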