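# nimopk

Population pharmacokinetics of the anti-EGFR monoclonal antibody
nimotuzumab in autosomal dominant polycystic kidney disease (ADPKD),
implemented as a quasi-steady-state (QSS) target-mediated drug disposition
(TMDD) model with two-site target binding and a clearance-stimulating
turnover mediator.

## Who this is for

Pharmacometricians and PK modellers who want a self-contained, tested
implementation of this model class: the ODE system and a fast compiled
solver, a virtual phase-I trial generator matching the original study
design, a Laplace nonlinear mixed-effects estimator with empirical Bayes
estimates and shrinkage, the standard evaluation toolbox
(prediction-corrected VPC, nonparametric bootstrap, weighted residuals,
stepwise covariate screening), and the deterministic dose-selection
analysis based on time above the QSS binding constant.

## The model

Free drug amounts in the central (A1) and peripheral (A2) compartments
follow a two-compartment model whose material balances are divided by the
QSS binding corrections `1 + Rtot*Kss/(Kss + C)^2` (constant total target
`Rtot` centrally, `Rtotp` peripherally, binding constant
`Kss = (koff + kint)/kon`), with bound central drug internalized at rate
`kint`. A latent turnover mediator A3 (baseline 1, synthesis stimulated by
the free central concentration through an Emax function with `Smax`, `S50`)
multiplies the non-specific clearance `CL`, reproducing the faster
elimination observed at higher doses. The observable is the total (free
plus bound) central concentration; residual error is additive on the log
scale, and inter-individual variability is log-normal on `Rtotp` and
`kout`. Default parameter values are the published population estimates
for nimotuzumab in ADPKD (units mg, L, h). Full equations, assumptions and
numerical choices are in the methods vignette
(`vignettes/qss-tmdd-methods.Rmd`).

## Worked example

Simulate the typical subject at the trial dose levels and derive the
dose-selection metrics:

```r
library(nimopk)
p <- nimo_params()          # published estimates; print(p) shows them all
sw <- dose_sweep(p, doses = c(50, 100, 200, 400, 800, 1200))
print(sw)
```

```
Dose-selection sweep (threshold 15.5 mg/L)
 dose cmax_free cmax_total auc_total time_above
   50  40.13065   40.13823  2717.665   62.64907
  100  37.87733   37.88478  4750.580  108.93269
  200  75.76073   75.76945  8724.284  167.81269
  400 151.52925  151.53877 16524.863  218.55512
  800 303.06777  303.07776 31992.110  266.15700
 1200 454.60725  454.61740 47405.736  293.33926
Percent increase in time above threshold between successive doses:
  50->100  100->200  200->400  400->800 800->1200 
     73.9      54.1      30.2      21.8      10.2 
```

`time_above` is the time (h) the free central concentration stays above
the binding constant Kss = 15.5 mg/L — the exposure metric behind the
published conclusion that 100 mg is the maximum effective single dose: the
percentage gained per dose doubling collapses as the mediator saturates.
The 50 mg arm uses its own cohort central volume (the published 53% V1
change, applied as a decrease — see the vignette for why), which is why its
peak concentration is not dose-proportional.

A complete virtual analysis — generate a 20-subject trial, fit it, run the
pc-VPC, the bootstrap and the sweep — is one call:

```r
report <- run_paper_pipeline(pipeline_config(seed = 20201147))
print(report)
```

There is also a thin command-line interface over the same functions
(`inst/cli/nimopk.R` with subcommands `generate`, `simulate`, `fit`,
`vpc`, `bootstrap`, `sweep`, `pipeline`).

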