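Package: levipop
Title: Population Pharmacokinetics of Intravenous Levetiracetam in
    Critically Ill Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of intravenous
    levetiracetam in critically ill patients with normal or augmented renal
    clearance. Implements a closed-form two-compartment infusion model with a
    creatinine-clearance covariate on clearance, log-normal interindividual
    variability and proportional residual error; nonlinear mixed-effects
    estimation by first-order conditional estimation with interaction
    (FOCE-I); stepwise covariate model building with forward/backward
    likelihood-ratio gates; nonparametric bootstrap; goodness-of-fit and
    prediction-corrected visual predictive check diagnostics;
    noncompartmental analysis with the linear-log trapezoidal rule; Monte
    Carlo probability-of-target-attainment evaluation of dosing regimens;
    and a synthetic-study generator emulating an intensive-care cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
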