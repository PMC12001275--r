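Package: vampk
Title: Variational Amortized Mixed-Effects Modeling for Population Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modeling in
    which a neural encoder amortizes inference of per-patient random effects.
    The encoder maps each patient's covariates and measured concentrations to
    a Gaussian posterior over log-normal inter-individual variability terms;
    individual parameters feed a mechanistic compartmental model (intravenous
    one-compartment with linear elimination, or an oral parent-metabolite
    system with first-pass hepatic extraction and allometric scaling), and
    the whole model is trained by minimizing a negative evidence lower bound
    with reparametrized sampling. Includes event-record data handling with
    study-specific exclusion filters, patient-level repeated cross-validation,
    prediction error metrics, prediction-corrected visual predictive checks,
    and virtual-cohort generators with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: deSolve, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
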