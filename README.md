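# gastropk

Population pharmacokinetics of gastroretentive (GR) drug delivery with
time-varying dissolution, in R.

Gastro-floating devices keep a sustained-release tablet in the stomach
so a drug with an upper-intestinal absorption window — acyclovir is the
motivating case — is delivered where it can be absorbed. The catch is
that in vitro dissolution testers do not reproduce how such a device
releases drug in vivo. `gastropk` implements the model-based
alternative: fit a population PK (POP-PK) model to plasma
concentration–time data and read the in vivo dissolution profile out of
the fitted model.

The structural model is a five-compartment system. Undissolved drug in
the GR system dissolves at a first-order rate that changes over time
through a Hill-type activation,

    Kdiss(t) = Kdiss(0) * [1 + Dissmax * (t - Tlag)^H / (Tchange50^H + (t - Tlag)^H)],

with `H = 10` (fixed), so release is biphasic: slow at `Kdiss(0)` until
about `Tchange50` hours after the lag, then fast at
`Kdiss(0)*(1 + Dissmax)`. Dissolved drug passes a transit compartment
(`Ka_trans`) and the gut (`Ka`) into a two-compartment disposition model
(`V1`, `V2`, `CL`, `CLD`), scaled by the relative bioavailability
`Frel`. Immediate-release (IR) doses enter the transit compartment
directly.

The package provides:

* `simulate_profile()`, `dissolution_profile()`, `t_percent_dissolved()`
  — forward simulation (deSolve or a compiled Dormand–Prince solver),
  model-predicted in vivo dissolution and T80;
* `nca()`, `frel()`, `lambda_z()`, `auc()` — non-compartmental analysis
  (Cmax, Tmax, AUC, λz, t½, MRT, CL/F, Vz/F, relative bioavailability);
* `fit_mcpem()`, `fit_two_stage()`, `bootstrap_se()` — population
  estimation with log-normal between-subject variability by
  importance-sampling Monte Carlo EM (MC-PEM), with a fast two-stage
  cross-check;
* `vpc()`, `gof_table()`, `pe_percent()`, `autoplot()` methods —
  simulation diagnostics;
* `study_design()`, `generate_cohort()`, `sample_individuals()`,
  `apply_lloq()` — virtual parallel-group dog studies with LLOQ
  censoring, for end-to-end validation;
* readers/writers for the delimited dataset, dissolution, estimate and
  simulation formats, and a thin command line (`exec/gastropk`) with
  `generate`, `simulate`, `dissolve`, `nca`, `fit` and `vpc`
  subcommands.

## Worked example

Simulate the GR system at the reference population estimates (100 mg
single oral dose in a Beagle dog) and extract the in vivo T80:

```r
library(gastropk)

p <- pk_params()   # reference estimates for the acyclovir GR system
p
#> <pk_params> (volumes L, clearances L/h, times h, rates 1/h)
#>        V1        V2        CL       CLD      Tlag    Kdiss0 Tchange50   Dissmax
#>    8.8300    3.4700    4.5700    1.7500    0.0189    0.0683    6.1500    7.8600
#>      Hill  Ka_trans        Ka      Frel
#>   10.0000    2.6300    2.6800    1.1900

sim <- simulate_profile(p, dose = 100, formulation = "GR",
                        times = c(0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48))
head(as.data.frame(sim[, 1:3]), 8)
#>   TIME_H CONC_UG_ML FRAC_DISSOLVED
#> 1   0.00    0.00000         0.0000
#> 2   0.25    0.00946         0.0157
#> 3   0.50    0.05975         0.0323
#> 4   1.00    0.26196         0.0648
#> 5   2.00    0.70166         0.1266
#> 6   4.00    1.10796         0.2400
#> 7   6.00    1.57466         0.4349
#> 8   8.00    3.09098         0.7785

diss <- dissolution_profile(p, dose = 100)
t_percent_dissolved(diss, 80)
#> [1] 8.18
```

The predicted in vivo T80 of about 8.2 h is roughly three times the
in vitro value of the same system (~2.5 h by the paddle method), and
the `FRAC_DISSOLVED` column shows the biphasic shape: barely 24% of the
dose is dissolved by 4 h, then the Hill activation raises the rate and
release completes within a few more hours. The plasma concentration
peaks late (around 8–12 h) for the same reason.

Relative bioavailability from group-mean `AUC_inf` values at equal
doses:

```r
frel(28.90, 23.56)   # GR system vs IR reference
#> [1] 122.67
```

A full round trip on synthetic data — generate a virtual study, fit it,
check the fit:

```r
est <- reference_estimate()
coh <- generate_cohort(study_design(n_subjects = 5, arms = c("IR", "GR"),
                                    seed = 1), est)
fit <- fit_mcpem(coh$data, est, n_samples = 500, n_iter = 40, seed = 1)
tidy(fit)              # estimate table: parameter, mean, BSV, fixed flags
autoplot(gof_table(fit, coh$data))
autoplot(vpc(fit, study_design(seed = 2), observed = coh$data))
```

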