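# Mechanistic compartmental models. States are drug AMOUNTS (mg); observed
# concentrations are amount / central volume. Doses always enter the first
# compartment; initial state is zero.

#' Right-hand side of the intravenous one-compartment model
#'
#' dA1/dt = rate - (CL/V) * A1, with `rate = D/IT` while an infusion is
#' running and 0 otherwise.
#'
#' @param state numeric, amount in the central compartment (mg).
#' @param t time (h); unused, the system is autonomous given the rate.
#' @param theta named list/vector with `CL` (L/h) and `V` (L).
#' @param infusion_rate zero-order input rate (mg/h).
#' @return Derivative of the state (mg/h).
#' @export
rhs_5fu <- function(state, t, theta, infusion_rate = 0) {
  infusion_rate - (theta[["CL"]] / theta[["V"]]) * state
}

#' Steady-state concentration under constant infusion
#'
#' Closed form of the one-compartment infusion model at dA/dt = 0:
#' `C_ss = D / (IT * CL)`, independent of the volume of distribution.
#'
#' @param D dose (mg).
#' @param IT infusion duration (h).
#' @param CL clearance (L/h).
#' @return Steady-state concentration (mg/L).
#' @export
css_5fu <- function(D, IT, CL) {
  if (any(D <= 0) || any(IT <= 0) || any(CL <= 0))
    stop("D, IT and CL must all be positive", call. = FALSE)
  D / (IT * CL)
}

#' Right-hand side of the oral parent-metabolite model
#'
#' Five states (mg): gut (A1), parent central (A2), parent peripheral (A3),
#' metabolite central (A4), metabolite peripheral (A5). Absorbed drug and
#' central parent returning through the liver mix into a liver-inflow
#' concentration
#' `C_LIV = (KA*A1 + (QH/V2S)*A2) / (QH + CLS)`;
#' hepatic extraction eliminates parent at rate `CLS*C_LIV`, of which the
#' fraction `FM` appears as metabolite (first-pass and systemic metabolism
#' through one hypothetical enzyme/liver construct).
#'
#' @param state numeric length 5.
#' @param t time (h); unused.
#' @param theta named vector/list with `KA, FM, CLS, QS, CLM, QM, QH, V2S,
#'   V3S, V2M, V3M`.
#' @return Derivative vector (mg/h).
#' @export
rhs_sunitinib <- function(state, t, theta) {
  th <- as.list(theta)
  A1 <- state[1L]; A2 <- state[2L]; A3 <- state[3L]
  A4 <- state[4L]; A5 <- state[5L]
  c_liv <- (th$KA * A1 + (th$QH / th$V2S) * A2) / (th$QH + th$CLS)
  dA1 <- -th$KA * A1
  dA2 <- th$QH * c_liv - (th$QH / th$V2S) * A2 -
    (th$QS / th$V2S) * A2 + (th$QS / th$V3S) * A3
  dA3 <- (th$QS / th$V2S) * A2 - (th$QS / th$V3S) * A3
  dA4 <- th$FM * th$CLS * c_liv - (th$CLM / th$V2M) * A4 -
    (th$QM / th$V2M) * A4 + (th$QM / th$V3M) * A5
  dA5 <- (th$QM / th$V2M) * A4 - (th$QM / th$V3M) * A5
  c(dA1, dA2, dA3, dA4, dA5)
}

#' Allometric scaling of the parent-metabolite parameters
#'
#' Clearances and intercompartmental flows (`CLS, QS, CLM, QM, QH`) scale
#' with `(weight/70)^0.75`, volumes (`V2S, V3S, V2M, V3M`) with `weight/70`;
#' `KA` and `FM` are size independent.
#'
#' @param theta named parameter vector (typical or individual values).
#' @param weight body weight in kg.
#' @return Scaled parameter vector.
#' @export
allometric_scale <- function(theta, weight) {
  if (is.na(weight) || weight <= 0)
    stop("allometric scaling needs a positive weight (impute upstream)",
         call. = FALSE)
  th <- unlist(theta)
  flows <- c("CLS", "QS", "CLM", "QM", "QH")
  vols <- c("V2S", "V3S", "V2M", "V3M")
  th[flows] <- th[flows] * (weight / 70)^0.75
  th[vols] <- th[vols] * (weight / 70)
  th
}

#' Structural model specification
#'
#' Registry entry bundling the ODE right-hand side, dosing semantics and the
#' observation map for a drug type. The first compartment always receives
#' the dose; observed concentrations are central amounts over central
#' volumes (parent = A2/V2S, metabolite = A4/V2M for sunitinib; A1/V for
#' the intravenous model).
#'
#' @param drug_type `"fu5"` or `"sunitinib"`.
#' @return A list of class `structural_model` with elements `drug_type`,
#'   `n_state`, `rhs`, `observe(state_matrix, theta)`, `analytes` and
#'   `closed_forms` (logical).
#' @export
structural_model <- function(drug_type = c("fu5", "sunitinib")) {
  drug_type <- match.arg(drug_type)
  if (drug_type == "fu5") {
    spec <- list(
      drug_type = "fu5", n_state = 1L,
      rhs = function(state, t, theta, infusion_rate = 0)
        rhs_5fu(state, t, theta, infusion_rate),
      observe = function(states, theta)
        cbind(parent = states[, 1L] / theta[["V"]]),
      analytes = "parent",
      closed_forms = TRUE)
  } else {
    spec <- list(
      drug_type = "sunitinib", n_state = 5L,
      rhs = function(state, t, theta, infusion_rate = 0) {
        d <- rhs_sunitinib(state, t, theta)
        d[1L] <- d[1L] + infusion_rate
        d
      },
      # amounts are mg and volumes L (mg/L); measured sunitinib
      # concentrations are ng/mL, hence the factor 1000
      observe = function(states, theta)
        cbind(parent = 1000 * states[, 2L] / theta[["V2S"]],
              metab = 1000 * states[, 4L] / theta[["V2M"]]),
      analytes = c("parent", "metab"),
      closed_forms = FALSE)
  }
  class(spec) <- "structural_model"
  spec
}

#' Solve a dosing regimen and observe concentrations
#'
#' Integrates the structural ODE system from a zero initial state at t = 0.
#' Oral doses are instantaneous additions to compartment 1 at their event
#' time; infusions are zero-order input into compartment 1 over their
#' duration. The integrator (stiff-capable `deSolve::lsoda`) is restarted at
#' every dose start and infusion end, so event times are exact mesh points.
#'
#' @param spec a [structural_model()].
#' @param theta named individual parameter vector (post allometric scaling
#'   where applicable).
#' @param regimen data frame with columns `time` (h), `amount` (mg),
#'   `duration` (h; 0 for an oral bolus), `route`.
#' @param times observation times (h), sorted, nonnegative.
#' @param rtol,atol solver tolerances; the system mixes half-lives of
#'   minutes with horizons of weeks, hence the tight defaults.
#' @return Matrix of concentrations, one row per time, one column per
#'   analyte (mg/L for `"fu5"`, amount/volume in the dataset's units
#'   otherwise).
#' @export
solve_profile <- function(spec, theta, regimen, times,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "structural_model"))
  if (nrow(regimen) == 0L) stop("regimen must be nonempty", call. = FALSE)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  theta <- unlist(theta)

  starts <- regimen$time
  ends <- regimen$time + regimen$duration
  breaks <- sort(unique(c(0, starts, ends[regimen$duration > 0],
                          times, max(times, ends, 0))))
  state <- rep(0, spec$n_state)
  out <- matrix(NA_real_, length(times), length(spec$analytes),
                dimnames = list(NULL, spec$analytes))
  record <- function(t_val, st) {
    hit <- which(times == t_val)
    if (length(hit) > 0L) {
      conc <- spec$observe(matrix(st, nrow = 1L), theta)
      out[hit, ] <<- matrix(rep(conc, length(hit)), length(hit),
                            byrow = TRUE)
    }
  }
  bolus_at <- function(t_val) {
    sum(regimen$amount[regimen$duration == 0 & regimen$time == t_val])
  }
  rate_in <- function(t_val) {
    act <- regimen$duration > 0 & regimen$time <= t_val &
      t_val < regimen$time + regimen$duration
    sum(regimen$amount[act] / regimen$duration[act])
  }

  state[1L] <- state[1L] + bolus_at(breaks[1L])
  record(breaks[1L], state)
  if (length(breaks) > 1L) {
    for (i in seq_len(length(breaks) - 1L)) {
      t0 <- breaks[i]; t1 <- breaks[i + 1L]
      rate <- rate_in((t0 + t1) / 2)
      sol <- suppressWarnings(deSolve::lsoda(
        y = state, times = c(t0, t1),
        func = function(t, y, parms)
          list(spec$rhs(y, t, theta, infusion_rate = rate)),
        parms = NULL, rtol = rtol, atol = atol, maxsteps = 5e4))
      if (attr(sol, "istate")[1L] < 0 || nrow(sol) < 2L)
        stop("ODE solver failed near t = ", t0, " h", call. = FALSE)
      state <- as.numeric(sol[nrow(sol), -1L])
      state[1L] <- state[1L] + bolus_at(t1)
      record(t1, state)
    }
  }
  if (any(out < -atol, na.rm = TRUE))
    stop("negative concentration beyond tolerance in solution",
         call. = FALSE)
  out[out < 0] <- 0
  out
}
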