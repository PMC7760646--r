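---
title: "Methods: a QSS TMDD model with a clearance-stimulating mediator"
author: "nimopk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a QSS TMDD model with a clearance-stimulating mediator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimopk)
```

## The model

Nimotuzumab is an anti-EGFR IgG1 antibody studied in adults with autosomal
dominant polycystic kidney disease (ADPKD), a condition in which EGFR is
overexpressed on cyst epithelium. After a single 30-minute intravenous
infusion its serum kinetics are nonlinear in dose, which is the signature of
target-mediated drug disposition (TMDD): a pharmacologically meaningful
fraction of the dose is bound and eliminated by the receptor itself.

`nimopk` implements the quasi-steady-state (QSS) reduction of the full TMDD
model with *constant total target* in two sites. Free drug amounts in the
central (`A1`, mg) and peripheral (`A2`, mg) compartments evolve as

$$
\frac{dA_1}{dt} =
\frac{\mathrm{in}(t)
  - \left(\frac{CL\,A_3}{V_1} + \frac{Q}{V_1}\right) A_1
  + \frac{Q}{V_2} A_2
  - \frac{k_{int} R_{tot} A_1}{K_{ss} + C_1}}
 {1 + \dfrac{R_{tot} K_{ss}}{(K_{ss} + C_1)^2}},
\qquad
\frac{dA_2}{dt} =
\frac{\frac{Q}{V_1} A_1 - \frac{Q}{V_2} A_2}
 {1 + \dfrac{R_{totp} K_{ss}}{(K_{ss} + C_2)^2}},
$$

with $C_1 = A_1/V_1$, $C_2 = A_2/V_2$. The denominators are the QSS
corrections for instantaneous re-equilibration of drug-target binding at
constant total target concentration ($R_{tot}$ centrally, $R_{totp}$
peripherally); they are $\ge 1$ for any non-negative state, equal 1 when the
target vanishes, and reduce the system exactly to the linear two-compartment
model when $R_{tot} = R_{totp} = 0$. Bound drug is internalized from the
central complex at rate $k_{int}$. The binding constant
$K_{ss} = (k_{off} + k_{int})/k_{on}$ exceeds the in-vitro dissociation
constant $K_d = k_{off}/k_{on}$ because the complex is removed in vivo;
with the published in-vitro rates $K_d \approx 2.1\times10^{-8}$ mol/L
(3.2 mg/L at 150 kDa) against $K_{ss} = 15.5$ mg/L.

The concentration dependence of clearance at higher doses is carried by a
latent turnover *mediator* $A_3$ (dimensionless, baseline 1):

$$
\frac{dA_3}{dt} = k_{in}\left(1 +
  \frac{S_{max} C_1^{\gamma}}{S_{50}^{\gamma} + C_1^{\gamma}}\right)
  - k_{out} A_3,
$$

which multiplies the non-specific clearance ($CL \cdot A_3$). The pre-dose
steady state $A_3(0) = 1$ forces $k_{in} = k_{out}$, so the synthesis rate
is never a free parameter, and $1 \le A_3 \le 1 + S_{max}$ always. The
observable is the assay's total concentration, free plus QSS-bound complex:
$C_1 + R_{tot} C_1 / (K_{ss} + C_1)$.

Two points in the printed model description are internally inconsistent and
required a decision:

* **Stimulation driver.** The mediator equation as printed drives the
  sigmoid with the central *amount*, while $S_{50}$ is defined and
  estimated as a *concentration* (mg/L). We drive it with $C_1$; this is
  the only unit-consistent reading.
* **Scope of the QSS denominators.** The printed one-line equations are
  typographically ambiguous about what the correction denominator divides.
  We divide the entire material balance of each binding compartment, the
  standard constant-target QSS form and the only dimensionally coherent one.
* **Hill coefficient.** No estimate of $\gamma$ is reported; the default is
  the minimal sigmoid $\gamma = 1$, configurable.

## Parameters, units, defaults

Units are mg, L and h throughout; time zero is the infusion start. The
defaults of `nimo_params()` are the published population estimates:
`CL` 9.64e-3 L/h, `V1` 2.63 L, `V2` 9.92e-3 L, `Q` 2.88e-2 L/h, `Kss`
15.5 mg/L, `kint` 4.94e-3 1/h, `Rtot` 1.05e-2 mg/L, `Rtotp` 956 mg/L,
`kout` 1.33e-2 1/h, `Smax` 3.18, `S50` 8.57 mg/L. Inter-individual
variability is exponential on `Rtotp` and `kout` with log-scale standard
deviations 1.35 and 1.97 (the "135%" and "197%" of the usual
pharmacometric reporting convention, $100\sqrt{\omega^2}$), and the
residual error is additive on natural-log concentration with SD 0.48
("48%"). These conventions are worth stating because the percentages are
conventions, not model equations.

### The 50 mg cohort volume

The reported fixed effects include a "V1 change" of 53% for the 50 mg
cohort, with no printed sign or functional form. Both readings are
implemented (`v1_dose50_mode`): `"decrease"` gives
$V_1 \times (1 - 0.53)$, `"increase"` gives $V_1 \times (1 + 0.53)$. Under
the increase reading the 50 mg profile peaks at 12.4 mg/L and never reaches
$K_{ss} = 15.5$ mg/L, so every time-above-threshold comparison against the
50 mg arm is undefined; under the decrease reading the 50 mg arm peaks near
40 mg/L and the comparisons are finite. The package therefore defaults to
`"decrease"`. Even so, the deterministic sweep at the published typical
values yields a 50→100 mg increase in time above $K_{ss}$ of about 74%
(not the published 150%) and a largest doubling gain above 100 mg of about
54% (not "< 25%"); `scripts/acceptance.R` recomputes and reports exactly
these quantities, and the corresponding acceptance assertions are expected
to fail. We were unable to find any reading of the printed equations and
estimates (amount- vs concentration-driven sigmoid, $\gamma \in \{1,2,3\}$,
swapped target concentrations, either V1 direction, either compartment's
series, free vs total concentration) that reproduces both published
percentages; the qualitative claim — gains per doubling shrink rapidly
above 100 mg — does hold.

## The virtual trial generator

`generate_trial()` emulates the phase-I design: 4 cohorts × 5 subjects at
50/100/200/400 mg, a 30-minute infusion, a pre-dose sample (kept as a
missing-value record) and 23 post-dose samples from 0.5 to 672 h. Covariates
(age, weight, height, BSA, serum creatinine, CrCL, total kidney and cyst
volumes, sex, race) are drawn log-normally with moments matched to the
published cohort table (total kidney volume sex-specifically; 70% female;
75% Caucasian). Under the final model they influence nothing — they exist
so covariate screening has an honest true-negative test bed — and effects
can be injected (`covariate_effects`) to create true positives. Observations
are `exp(log(C_total) + eps)`, so they are strictly positive; the assay's
quantification limit (7.8 ng/mL) is carried but inert, because no
observation fell below it in the study and none does under the default
parameters unless flagged deliberately (`apply_lloq`).

The generator's default produces the complete 20 × 23 = 460-observation
schedule. The original analysis had 422 observations with an unreported
missingness pattern; we do not emulate it. What passing tests on generated
data do *not* show: robustness to dropout, to assay censoring, to sampling
time deviations, or to model misspecification beyond the cases explicitly
constructed.

## Estimation

`nimo_fit()` maximises a Laplace-approximated marginal likelihood — the
same model and error structure as the original SAEM/importance-sampling
analysis, with a different (deterministic) integrator for the random
effects, which is a documented contract substitution. For each subject the
joint $-2\log$(likelihood × random-effect density) is minimised over
$\eta = (\eta_{R_{totp}}, \eta_{k_{out}})$; the curvature at the mode
supplies the Gaussian integral correction
$-2\log L_i = g(\hat\eta) - q\log 2\pi + \log\det H - q\log 2$. With
$\Omega \to 0$ this reduces exactly to the likelihood at the typical
values, a cancellation the tests exercise.

Numerical choices that matter:

* **Fixed-grid likelihood integration.** Inside the likelihood the ODE is
  integrated with fifth-order Dormand-Prince steps on a grid determined by
  the schedule (fine through infusion and distribution, coarser terminally,
  capped by a local stability bound) rather than by adaptive error
  control. Error control makes the accepted-step sequence, and hence the
  objective, a discontinuous function of the parameters at the 1e-4 level
  — enough to defeat finite-difference gradients. The fixed grid is smooth
  in the parameters and accurate to ~1e-5 relative against a tight
  adaptive reference; `simulate` paths keep adaptive error control.
* **Gauss-Newton inner curvature.** The inner Newton iterations and the
  Laplace determinant use $2J^{\top}J/\sigma^2 + 2\Omega^{-1}$ from the
  Jacobian of the log-prediction — positive definite by construction and
  obtained from the same solves as the gradient. The exact
  finite-difference Hessian is available (`marginal_neg2ll(hessian =
  "exact")`) and is what the quadrature-agreement tests use.
* **Outer optimisation** runs on log-transformed parameters (logit for the
  bounded 50 mg V1 fraction): an optional Nelder-Mead bracketing phase,
  then BFGS with wide-step central-difference gradients. The per-subject
  mode estimates are advanced only when the objective improves, so
  exploratory side evaluations cannot poison the warm starts.
* **Identifiability at n = 20.** `Kss`, `kint`, `Rtot` and `gamma` are
  fixed at their published values by default: a single-dose 20-subject
  design does not identify them jointly with the rest. In the recovery,
  bootstrap and screening test workflows `Q` and `V2` are additionally
  fixed — the peripheral volume is 0.4% of the central volume and trades
  off almost freely against `Rtotp` and `S50` at this sample size. All
  published values remain estimable on request.

Empirical Bayes estimates, eta-shrinkage ($100(1 - \mathrm{SD}(\hat\eta)/
\omega)$) and epsilon-shrinkage ($100(1 - \mathrm{SD}(\mathrm{IWRES}))$)
are reported with every fit. Nested models are compared at
$\Delta\mathrm{OFV} \ge 7.879$ per degree of freedom ($p = 0.005$),
non-nested by AIC. Stepwise covariate screening adds terms forward at
$\Delta\mathrm{OFV} \ge 3.84$ and eliminates backward at $\ge 6.63$, with
power forms for continuous covariates (centered on the data median) and
fractional shifts for categorical ones — the pharmacometric convention,
as the source analysis does not state its functional forms. Parameters
carrying a random effect are screened only when their eta-shrinkage is
below 35%.

## Model evaluation

The prediction-corrected VPC simulates replicate trials on the observed
design and corrects each observation and simulated value by
`median(PRED in bin)/PRED`, multiplicative on the natural scale and hence
additive on the log scale, consistent with the residual model. Bins default
to the nominal sampling times (the design is balanced, so each time is a
bin; the original binning is unreported). The default is 1000 replicates;
the test suite uses 200, which the calibration experiments show is enough
for the 95% median band to cover the observed median in well over 90% of
bins under the true model. The nonparametric bootstrap resamples subjects
with replacement to the original size and refits each replicate from the
original point estimates (default 500 replicates; the test workflows use
100); replicates that fail are counted and the result is flagged when more
than 20% fail. Conditional weighted residuals come from a first-order
linearization of the log-prediction around the empirical Bayes estimates;
the exact NONMEM CWRESI algorithm is not reproduced.

## Dose selection

`dose_sweep()` runs the deterministic typical-subject simulation at 50,
100, 200, 400, 800 and 1200 mg over 1000 h on a 0.5 h grid (crossings
interpolated linearly) and reports $C_{max}$, trapezoidal AUC and the time
above $K_{ss}$, with the percent gain between successive doses. Under the
published values the gain per doubling collapses from hundreds of percent
(50→100) to ~10% (800→1200) as the mediator saturates — the quantitative
basis for 100 mg as the maximum effective dose, even though the exact
published percentages do not reproduce (see above).

## Problem sizes used by the tests

The automated suite generates all data programmatically: 20-subject trials
for recovery (10 seeds), calibration (5 seeds × 200 VPC replicates), one
100-resample bootstrap, ten screening seeds, and smaller 8-subject trials
for structural tests; these sizes were chosen so the full battery runs on a
single CPU in tens of minutes while leaving the Monte-Carlo error well
below the tolerances asserted.

## Known limitations

* The mediator is phenomenological; `Rtot` and `Rtotp` are apparent
  binding capacities, not receptor measurements, and EGFR turnover
  (`k_syn`/`k_deg`) is deliberately out of scope because the source
  analysis held target concentrations constant.
* Laplace (and its Gauss-Newton variant) is an approximation; with
  $\omega_{k_{out}} \approx 2$ the per-subject integrals are wide, and
  small-sample bias in the variance components should be expected.
* Single-dose regimens only are validated; the event engine accepts
  multiple doses but no claims attach.
* Off-diagonal random-effect covariance is supported structurally but
  disabled by default, mirroring the final published model.
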