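# shared fixture builders (all data generated in code)

# minimal event table for the intravenous design: one infusion at t = 0
# per patient, observations in the steady-state window
toy_fu5_events <- function(ids, doses, times, values, dur = 24,
                           wt = 75, sex = 1) {
  rows <- list()
  for (i in seq_along(ids)) {
    tt <- times[[i]]; vv <- values[[i]]
    rows[[i]] <- data.frame(
      ID = ids[i],
      TIME = c(0, tt), EVT = c("dose", rep("obs", length(tt))),
      AMT = c(doses[i], rep(NA, length(tt))),
      DUR = c(dur, rep(NA, length(tt))),
      DV = c(NA, vv), ANALYTE = c("", rep("parent", length(tt))),
      BLQ = c(NA, rep(0, length(tt))),
      SEX = if (length(sex) > 1) sex[i] else sex,
      AGE = 60, WT = if (length(wt) > 1) wt[i] else wt,
      HT = 170, BSA = 1.9, LBM = 55, FM = 20,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

toy_fu5_dataset <- function() {
  ev <- toy_fu5_events(ids = c("A", "B", "C"),
                       doses = c(4000, 3500, 4500),
                       times = list(c(18, 22), 20, c(17, 21, 24)),
                       values = list(c(0.70, 0.80), 0.75,
                                     c(0.65, 0.72, 0.78)))
  pk_dataset(ev, drug_type = "fu5")
}

# fast-fit control for tests
quick_control <- function(epochs = 60, ...) {
  vampk_control(epochs = epochs, patience = epochs, val_fraction = 0, ...)
}

# numerical gradient of f at x (central differences), for gradient checks
num_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
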