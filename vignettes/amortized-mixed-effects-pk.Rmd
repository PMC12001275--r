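---
title: "Amortized variational inference for population pharmacokinetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amortized variational inference for population PK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vampk)
```

## The model

`vampk` implements nonlinear mixed-effects population pharmacokinetics
with amortized variational inference of the random effects. The
parameter model is the classical one: for a parameter set $J$ with an
IIV subset $K \subseteq J$,

$$\vartheta_{k,i} = \begin{cases}
  \mathrm{TV}_k \, e^{\eta_{k,i}} & k \in K\\
  \mathrm{TV}_k & k \in J \setminus K,
\end{cases}$$

with $\eta_{k,i} \sim N(0, \lambda^2)$ a priori. The log-normal
construction guarantees positive individual parameters for any finite
$\eta$. A subset $L \subseteq J$ of the typical values is learned (in
the log domain); the rest are fixed, either because they are
structurally non-identifiable from the sampling design (the volume of
distribution of the intravenous model, fixed at 46.1 L, cannot be
identified from steady-state samples) or because they come from an
established prior model (the fraction metabolized and liver blood flow
of the oral model).

Instead of approximating the marginal likelihood (FOCE/SAEM), an
encoder network $\phi$ maps each patient's data to the mean and
log-variance of a diagonal Gaussian posterior over $\eta_i$. Training
minimizes the negative evidence lower bound with the reparametrization
trick ($\eta = \mu + \sigma z$, $z \sim N(0,1)$, one draw per unit per
step):

$$\ell = \frac{1}{n}\sum_i \Big[ \sum_{t}
  \frac{(y_{i,t}-\tilde y_{i,t})^2}{2\varepsilon_{i,t}^2}
  + \sum_{k\in K} \mathrm{KL}\!\left(q(\eta_{k,i}) \,\|\,
  N(0,\lambda^2)\right)\Big],$$

where $\tilde y$ solves the structural ODE system from a zero initial
state with all doses entering the first compartment. The KL term has
the closed form
$\tfrac12(\sigma^2/\lambda^2 + \mu^2/\lambda^2 - 1 +
\log(\lambda^2/\sigma^2))$, verified in the tests against Monte-Carlo
estimates, and the whole objective is verified against an
independently coded brute-force loop to $10^{-10}$.

Two conventions in the loss deserve comment.

* **Residual error.** The default error model is
  prediction-proportional, $\varepsilon = b\,\tilde y$; the literal
  observation-proportional variant $\varepsilon^2 \propto y$ is
  available by configuration (`loss_config(error_model =
  "prop_to_obs")`). The reconstruction term as defined above contains
  no normalizing constant, which is fine while $b$ is fixed — but a
  learned $b$ is unidentifiable without it (the term is monotone
  decreasing in $b$). When `learn_b = TRUE` (the default) the training
  objective therefore adds the Gaussian log-normalizer
  $\sum \log \varepsilon$; `reconstruction_nll()` itself stays the
  pure weighted sum of squares, and the loss decomposition reports the
  normalizer separately.
* **Summation structure.** The objective is the standard negative
  ELBO: the data term once per observation plus one KL per IIV
  parameter, averaged over sampling units. Published descriptions of
  this family of models sometimes typeset the data term inside the sum
  over $K$; that reading double-counts the likelihood $|K|$ times and
  contradicts the declared "negative ELBO", so it is not used.

## Drug-specific architecture

**Intravenous steady state (`"fu5"`).** Samples are drawn at steady
state during a constant-rate infusion, where the one-compartment model
admits the closed form $C_{ss} = D/(IT \cdot CL)$, independent of $V$.
Each measurement is treated as its own training sample; the encoder
input is the concatenation of the measured concentration, dose, and the
static covariates (weight, lean body mass, fat mass, BSA, age, sex,
height) with a missing-value mask. Concentration and dose enter on the
log scale — they are log-normal quantities, and on that scale the ideal
posterior-mean map is nearly linear in the inputs. The network is a
two-layer feed-forward trunk with SiLU activations plus a
zero-initialized *linear skip connection* from the standardized input
straight into the two heads ($\mu$ and $\log\sigma^2$). The skip keeps
extrapolation linear outside the training range; without it we observed
confident nonsense posteriors for test patients in sparsely covered
corners of covariate space. Training and prediction use the
steady-state closed form, which the tests pin to the ODE solution
within $10^{-6}$ relative; the general ODE path remains available
through `solve_profile()`.

Because the encoder sees the very measurement it is asked to
reconstruct — the design choice of the per-measurement encoding — its
"predictions" on observed samples are partly an inversion of the
observation. This is documented behavior, not leakage we introduced;
`predict(fit, encoding = "loo")` provides a leave-measurement-out mode
for honest prediction experiments, and the random-effect recovery
results below are reported on held-out patients.

**Oral parent + metabolite (`"sunitinib"`).** The structural system has
five amount states (gut; parent central/peripheral; metabolite
central/peripheral). Absorbed drug and recirculating central parent mix
into a liver-inflow concentration

$$C_{LIV} = \frac{K_A A_1 + (Q_H/V_{2S}) A_2}{Q_H + CL_S},$$

from which parent is eliminated at rate $CL_S \, C_{LIV}$ and a
fraction $F_M$ emerges as metabolite — a single hypothetical
enzyme/liver construct that covers both first-pass and systemic
metabolism. This is the only dimensionally consistent reading of the
published system, whose inline typesetting collapses the fraction bar.
Flows ($CL_S, Q_S, CL_M, Q_M, Q_H$) scale allometrically with
$(\mathrm{WT}/70)^{0.75}$ and volumes with $\mathrm{WT}/70$; $K_A$ and
$F_M$ are size-independent. $Q_H$ is fixed at a typical liver blood
flow (80 L/h) and then allometrically scaled per patient, resolving the
apparent tension between "fixed to liver blood flow" and "scaled".
Observed concentrations are mapped from the central amounts
(parent $= A_2/V_{2S}$, metabolite $= A_4/V_{2M}$, with the mg/L to
ng/mL factor); the source system never states its observation map, so
the standard central-compartment map is an explicit assumption.
Several typical values of this arm are not printed in the available
sources; the shipped defaults (`default_popset("sunitinib")`) are
documented, plausible placeholders and are meant to be overridden when
reference values are at hand.

The encoder has three blocks: a feed-forward block for the static
covariates (+mask), a time-gated LSTM over the irregularly sampled
(Δt, parent, metabolite) sequence, and a projection block with two
subnetworks emitting the $|K| = 4$ means and log-variances. The cited
time-aware recurrent cell exists in several variants and its internals
are not specified; we implement the memory-decay form: the previous
cell state is discounted by $\exp(-\mathrm{softplus}(d)\,\Delta t/24)$
(per-unit learned $d$, Δt in hours scaled to days) before a standard
LSTM gate update. At $\Delta t = 0$ the step reduces *exactly* to a
plain LSTM step, which is the tested neutrality property, and unequal
observation gaps provably change the encoding.

## Training and numerics

* **Optimizer**: Adam, step size $10^{-3}$, global gradient-norm
  clipping at 1.0, decoupled weight decay $10^{-3}$ on the encoder
  weights only (never on typical values or $b$). Up to 1000 epochs with
  early stopping (patience 200) on a 10% patient-level validation
  split. The validation criterion is the *same sampled ELBO* with a
  frozen noise draw; an earlier deterministic variant evaluated at
  $\eta = \mu$ systematically rewarded prior-collapsed encoders and
  stopped training far too early.
* **Gradients**: all network gradients are analytic reverse-mode
  (including backpropagation through time in the recurrent cell), and
  are verified against central finite differences in the test suite.
  For the oral design, the sensitivity of the data term to the sampled
  $\eta_k$ and to learned typical values without IIV is obtained by
  central finite differences through the ODE solve (step $10^{-4}$ in
  the log domain; for $k \in K \cap L$ the $\eta_k$ sensitivity *is*
  the $\log TV_k$ gradient, halving the extra solves). This trades a
  handful of additional ODE solves per patient per step for not having
  to differentiate the solver.
* **Widths**: hidden widths default to 32 units (two layers). With the
  ~500-sample cohorts these designs produce, 64-unit blocks overfit
  measurably — held-out random-effect correlation dropped by up to 0.1
  and occasionally collapsed — while 32 units with weight decay and the
  linear skip track the statistical oracle closely.
* **Solver**: stiff-capable `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10` for profile computation (the intravenous system mixes
  a 0.14 h half-life with 24 h horizons) and `1e-6 / 1e-8` inside
  training loops; the integrator restarts at every dose start and
  infusion end so event times are exact mesh points. Oral doses are
  instantaneous additions to the gut compartment; infusions are
  piecewise-constant zero-order input.
* **Determinism**: every stochastic entry point (`vampk()`,
  `simulate()`, `split_cv()`, generators) takes a mandatory seed,
  restores the caller's RNG state, and reproduces its output exactly
  under the same seed.

## The virtual cohorts: what they emulate and what they do not

The real cohorts behind both designs are not public, so validation
rests on generators with known ground truth.

The intravenous cohort reproduces the published design margins: 157
patients by default, male fraction 96/156, age median 64.5 (35–83),
BSA median 1.915 (1.35–2.85) m² with weight/height consistent through
the Du Bois relation and body composition by the James lean-body-mass
formula; BSA-proportional dosing (≈2100 mg/m², clipped to the observed
2700–5720 mg range, median ≈4000 mg); 1–9 samples per patient (median
3) drawn uniformly in the 16.8–25.0 h steady-state window; true
clearance $(TV + \beta_{BSA}(BSA - 1.915))e^{\eta}$ with
$\omega = 0.3$ and proportional noise $b = 0.2$. The published BSA
coefficient is not printed; the default slope $TV/1.915 \approx 116$
L/h/m² is the linearization of clearance proportional to BSA. Because
the nominal 24 h infusion would be finished (and the drug, with its
\~9 min half-life, long gone) for samples recorded after hour 24, the
generator models the infusion as continuing at its nominal rate
$D/IT$ through the sampling window; the event table records the
nominal dose and duration. One weekly occasion is simulated with
constant clearance across occasions (no inter-occasion variability,
matching the source analyses). Noise-free concentrations always come
from `solve_profile()` — the tests audit that the generator does not
re-implement the model.

The oral cohort reproduces 37.5/50 mg daily dosing on the
4-weeks-on/2-weeks-off schedule, trough sampling 30 min before intake
over at most a configurable number of cycles, 1–14 samples per patient
(median ≈6.5), paired parent/metabolite observations with per-analyte
proportional noise, covariate missingness at 12.9% (weight), 10.9%
(height) and 6.6% (BSA), and the 0.06 ng/mL quantification limit. The
demographics of this arm are not published in full; its covariate
distributions are implementer defaults. Both generators accept
`concentrations = FALSE` to produce covariates, regimens and
ground-truth parameters without ODE solves, which keeps large-n
demographic checks (e.g., missingness rates at n = 5000) fast.

Two deterministic fixtures (`generate_acceptance_fixture_*`) are
*synthetic stand-ins* that reproduce the published preprocessing
bookkeeping exactly: 157 patients / 549 observations of which 8 (on 8
distinct patients, exactly one losing their only sample) violate the
exclusion rules, leaving 541/156; and 47 patients / 308+308 paired
observations with 6 below-quantification parent values on 5 patients,
leaving 302 of each (1.95% excluded). Violating values are placed far
from the thresholds (≤0.8× the limit) so no rounding ambiguity exists,
and all other values are clamped safely clear of both rules.

What passing these checks does **not** show: that the method works on
real therapeutic-drug-monitoring data. The generators draw independent
covariates, log-normal IIV with diagonal structure, and exactly the
residual model the loss assumes; real cohorts have correlated
covariates and random effects, model misspecification, occasion
effects, assay artifacts, and informative sampling. The recovery and
calibration experiments are well-specified-model sanity checks, not
clinical validation.

## Evaluation protocol

Cross-validation follows the repeated patient-level design: 10
independent repeats of 5-fold splits (an 80/20 train/test ratio),
every patient strictly on one side of each split; weight imputation
for the oral design uses training-fold means by sex, and encoder
normalization statistics come from training folds only. Fold metrics
(MAE, RMSE) aggregate as mean ± sample SD over all repeat × fold
cells; whether the published SDs pool 50 folds or 10 repeat averages
is not stated, so pooling over all folds is the default and per-repeat
aggregation is a one-liner on the returned fold table.

The prediction-corrected VPC uses the Bergstrand construction: within
each time bin, observed and simulated values are rescaled by the
bin-median typical prediction over the observation's own typical
prediction (typical = all random effects zero); observed 5th/50th/95th
percentiles are compared with the 90% band of the same percentile
across replicates. The intravenous design defaults to a single
steady-state bin (all samples share the 16.8–25 h window); the oral
design defaults to equal-count time bins. Replicates for the
calibration experiment are drawn from the encoder posteriors with
residual noise; population-prior sampling ($\eta \sim N(0,\lambda^2)$)
is the other supported mode, since the source never states which
distribution its simulations used.

Two experiment-design decisions for the recovery and calibration runs:
they use a generator without the BSA covariate effect (a
*well-specified* model), because the fitted model has no covariate
term — with the BSA effect on, the encoder's $\eta$ must absorb the
covariate signal and the generator's $\eta$ is no longer the model's
estimand; and "held-out patients" for the random-effect correlation
are a freshly drawn cohort from the same population, the natural
generalization test for an amortized encoder. Problem sizes are 150
training / 100 test patients for recovery and 20 replicate
simulate-fit-check experiments of 100 patients with 500 simulation
replicates each for the VPC calibration.

## Known limitations

* The oral-design fit is computationally the weak point: R-level ODE
  solves with finite-difference sensitivities make it one to two
  orders of magnitude slower than the intravenous fit. It is correct
  and deterministic, but cohort-scale training is patient work;
  adjoint or matrix-exponential acceleration is the obvious next step.
* Posteriors are per-parameter diagonal Gaussians; correlated random
  effects (a block omega matrix) are out of scope.
* The per-measurement encoding of the steady-state design means
  in-sample predictive metrics measure reconstruction, not forecasting
  — use the leave-measurement-out mode or held-out patients for honest
  assessment.
* $F_M$ is constructed as $TV_{FM} e^{\eta}$ like every other IIV
  parameter; extreme positive $\eta$ draws can push an individual
  fraction metabolized above 1. The prior and the data keep fitted
  values in range, but the constraint is not structural.
* No inter-occasion variability, transit-compartment absorption, lag
  times, or enterohepatic recirculation.
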