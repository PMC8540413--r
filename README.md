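# levipop

Population pharmacokinetics of intravenous levetiracetam in critically ill
patients with normal or augmented renal clearance (ARC).

Levetiracetam is cleared mainly by the kidney, and ICU patients frequently
develop ARC (urinary creatinine clearance, CrCl, above 130 mL/min), which can
drive trough concentrations below the 12–46 mg/L reference range (or the
more permissive > 6 mg/L target). `levipop` implements the full analysis
pipeline for this problem:

* a **two-compartment IV-infusion model** (closed-form, macro-constant
  parameterisation) whose clearance carries an additive power covariate in
  renal function,

  CL (L/h) = (θ_nr + (CrCl/120)^θ_r) · e^η1,  V1 (L) = θ_V1 · e^η2,

  with the published final estimates θ_nr = 3.5 L/h, θ_r = 2.5,
  V1 = 20.7 L, Q = 31.9 L/h, V2 = 33.5 L, log-scale IIV SDs ω_CL = 0.327
  and ω_V1 = 0.561, and proportional residual error σ = 0.223, so typical
  clearance rises from 4.5 L/h at CrCl 120 to 9.2 L/h at CrCl 240;
* **nonlinear mixed-effects estimation** by FOCE-I (first-order conditional
  estimation with interaction; a Laplace option is available as a
  cross-check), with Hessian-based standard errors, empirical Bayes
  estimates and shrinkage;
* **stepwise covariate modelling** (forward ΔOFV ≥ 3.84, backward ≤ 6.63)
  and a **nonparametric bootstrap**;
* **diagnostics**: conditional weighted residuals (CWRES), goodness-of-fit
  tables/plots and a prediction-corrected visual predictive check (pcVPC);
* **noncompartmental analysis** (linear-log trapezoidal AUC within the
  dosing interval, best-adjusted-R² terminal slope, CL = dose/AUC_τ, Vz);
* **Monte Carlo probability of target attainment (PTA)**: steady-state
  troughs of 1000 virtual subjects per CrCl group (80–240 mL/min) against
  the 6/12/46 mg/L targets for 500–2000 mg given every 12 or 8 h as 30-min
  (or extended 2-h) infusions;
* a **synthetic-study generator** that reproduces the design of the source
  cohort (27 subjects, 500/1000/1500 mg q12h, six samples per subject at
  steady state, LLOQ 2 mg/L, covariates matched to the reported medians and
  ranges), so every stage of the pipeline is testable without patient data.

## Worked example

```r
library(levipop)

# a virtual 27-subject ICU study from the published final model
d <- generate_study(seed = 42)
d
#> pk_dataset: 27 subjects, 27 dose rows, 146 observations (0 BLOQ)

fit <- fit_foce(d, final_model())
fit
#> FOCE-I fit: 27 subjects, 146 observations, OFV = 511.893 (converged)
#>            estimate rse_pct
#> theta_nr     3.8500     9.3
#> theta_r      2.5640    20.1
#> v1          26.7600    14.3
#> q           20.0000    20.8
#> v2          34.5600    12.4
#> omega_cl     0.3553    14.4
#> omega_v1     0.6062    18.6
#> sigma_prop   0.1970     8.0
#> eta shrinkage (%): cl 1.1, v1 13.8; eps shrinkage 16.9
```

The fit recovers the generating model within the sampling noise of a
27-subject cohort: a clearance intercept of 3.85 L/h (truth 3.5), a CrCl
exponent of 2.56 (truth 2.5), and IIV/residual estimates near 0.327/0.561
and 0.223. Dosing evaluation:

```r
cfg <- pta_config(crcl_groups = c(120, 240), regimens = list(
  dosing_regimen(1000, tau = 12, steady_state = TRUE),
  dosing_regimen(2000, tau = 8, steady_state = TRUE)))
res <- simulate_pta(cfg, final_model(), seed = 42)
writeLines(pta_table(res)$text)
#> CrCl (mL/min) | Dose (mg) | Perfusion (h) | Tau (h) | Daily dose (mg) | >6 | >12 | >46
#> --- | --- | --- | --- | --- | --- | --- | ---
#> 120 | 1000 | 0.5 | 12 | 2000 | **85** | 43 | 0
#> 120 | 2000 | 0.5 | 8 | 6000 | **100** | **98** | 35
#> 240 | 1000 | 0.5 | 12 | 2000 | 15 | 1 | 0
#> 240 | 2000 | 0.5 | 8 | 6000 | **89** | 57 | 1
```

Read: 1000 mg every 12 h keeps 85% of virtual patients with normal renal
function (CrCl 120) above the 6 mg/L trough but only 43% above 12 mg/L,
while at CrCl 240 even 2000 mg every 8 h leaves the 12 mg/L target mostly
unmet (57%) — the ARC under-dosing problem the analysis quantifies. Bold
cells mark probabilities ≥ 80%.

A thin command-line wrapper over the same functions is installed at
`inst/cli/levipop.R` (`synth`, `simulate`, `fit`, `nca`, `vpc`, `pta`
subcommands, each taking `--seed`, `--config`, `--out`).

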