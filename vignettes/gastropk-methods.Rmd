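---
title: "Model and methods behind gastropk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gastropk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastropk)
```

## The problem

Gastroretentive (GR) delivery systems hold a sustained-release tablet in
the stomach so a drug with an upper-intestinal absorption window — here
acyclovir — keeps being delivered to the site where it can be absorbed.
In vitro dissolution testers systematically misjudge how such a device
releases drug in vivo: the device constrains tablet swelling, gastric
contents change the hydrodynamics, and the resulting in vivo release can
be biphasic where the in vitro curve is monophasic. `gastropk`
implements the model-based route around this: estimate a population
pharmacokinetic (POP-PK) model from plasma concentration–time data and
read the in vivo dissolution profile out of the fitted model.

## Structural model

Six state variables track drug amounts (mg): the undissolved depot in
the GR system, a transit compartment, the absorbing gut compartment, the
central and peripheral disposition compartments, and a cumulative
elimination bookkeeping term (not part of the biology; it makes the mass
balance an assertable invariant). Dissolution from the GR system is
first order with a time-varying rate constant

$$K_{diss}(t) = K_{diss}(0)\left[1 + Diss_{max}\,
\frac{(t-T_{lag})^{H}}{T_{change50}^{H} + (t-T_{lag})^{H}}\right],
\qquad t > T_{lag},$$

and zero up to the lag time $T_{lag}$. With the conventional Hill
coefficient $H = 10$ the activation is near switch-like: the rate stays
at $K_{diss}(0)$ for roughly $T_{change50}$ hours after the lag and then
rises to $K_{diss}(0)(1+Diss_{max})$, which reproduces the observed
biphasic (slow-then-fast) in vivo release. Dissolved drug enters the
transit compartment scaled by the relative bioavailability $F_{rel}$,
moves to the gut at rate $K_{a,trans}$, is absorbed at rate $K_a$, and
disposes through a standard two-compartment model with clearances $CL$
(elimination) and $CL_D$ (distribution) and volumes $V_1$, $V_2$.
Immediate-release (IR) dosing skips the depot: the dose is placed in the
transit compartment directly, and the dissolution machinery never enters
the IR equations.

Three modelling choices deserve a note:

* **Behaviour at the lag.** With an even Hill power the activation term
  is formally symmetric around $T_{lag}$; we gate dissolution to exactly
  zero for $t \le T_{lag}$ and evaluate the Hill argument on
  $t - T_{lag} > 0$ only. At the reference estimate
  ($T_{lag} = 0.0189$ h, about 1.13 min) the numerical impact is
  negligible, but the gate keeps the semantics well defined for large
  lags.
* **The lag applies to GR dissolution only.** The IR transit input has
  no lag; the transit compartment itself supplies the short initial
  delay seen after IR dosing.
* **Dissolution from the state.** The fraction dissolved is read off
  the simulated depot, $1 - X_{GR}(t)/\text{dose}$, rather than
  integrated separately, so the concentration and dissolution outputs of
  one simulation can never disagree. The in vivo $T_{80}$ is the
  linearly interpolated first crossing of 80%; a curve that never
  attains the target yields `NA` with a warning, never an extrapolation.

Units are hours, milligrams, litres and L/h throughout; concentrations
come out in mg/L, numerically identical to the reported ug/mL.

## Numerics

The user-facing `simulate_profile()` defaults to `deSolve::lsoda` with
relative tolerance 1e-8 and absolute tolerance 1e-10 mg, with evaluation
forced at the lag and at the activation midpoint so the adaptive solver
cannot step across the near-switch. Estimation needs millions of small
solves, far beyond what an interpreted right-hand side supports, so the
package also carries a compiled Dormand–Prince 5(4) integrator (the
`"rk45"` engine) that restarts at the lag; the same code path powers the
likelihood kernel. The two engines are cross-checked against each other
and against the closed-form biexponential bolus solution (the
`analytic_two_compartment()` oracle) to 1e-6 relative error in the test
suite, and every simulated trajectory must conserve
$F_{rel} X_{GR} + X_{trans} + X_{gut} + X_c + X_p + X_{elim} =
F_{rel}\,\text{dose}$ to within 1e-6 of the dose. Inside estimation the
integration tolerance is relaxed to 1e-5/1e-7: the Monte Carlo noise of
the E-step dominates solver error by orders of magnitude there, and the
reporting path keeps the tight tolerance.

## Non-compartmental analysis

`nca()` reproduces the standard parameter set: $C_{max}$ and $T_{max}$
read directly from the observations; $\lambda_z$ by log-linear
regression over the contiguous terminal run of at least three
quantifiable post-$C_{max}$ points (excluding $C_{max}$) with the best
adjusted $r^2$, ties within 1e-4 resolved toward more points — the
"best fit" convention of the widely used NCA software; linear
trapezoidal AUC by default with a linear-up/log-down option;
$AUC_\infty = AUC_{all} + C_{last}/\lambda_z$; extravascular
$MRT = AUMC_\infty / AUC_\infty$ without a mean-absorption-time
correction; $CL/F$ reported in mL/min (1 L/h = 16.667 mL/min); and
relative bioavailability as the dose-normalised $AUC_\infty$ ratio
against the IR reference. Pre-dose and leading below-quantification
(BLQ) records enter the AUC as zeros; embedded and trailing BLQ records
are excluded. None of these conventions is dictated by the data — they
are the package's documented defaults, chosen to match common practice.

## Population estimation

Between-subject variability (BSV) follows the exponential model
$\theta_i = \theta_{pop} e^{\eta_i}$ with independent
$\eta_i \sim N(0, \omega^2)$ per parameter. Throughout the package the
BSV column of an estimate table is the **variance** $\omega^2$ of the
log-scale random effect, not its standard deviation. The residual model
is Gaussian on the concentration scale with
$sd = \sqrt{\sigma_{add}^2 + (\sigma_{prop} f)^2}$; the default is
purely proportional, which matches the percent-scale precision of
plasma assays. BLQ records (below 0.05 ug/mL) are dropped from the
likelihood — the simplest defensible rule at this censoring intensity.
`Hill` and `Frel_IR` are fixed (10 and 1) and no fit may move them.
Because $F_{rel}$ multiplies only the GR dissolution input, the IR
bioavailability never enters the IR equations; the BSV listed for it in
the reference table is carried for completeness but cannot be informed
by data under this model. The `Dissmax` random effect is log-normal,
which presumes a positive population value (as estimated here) and
automatically respects $1 + Diss_{max} \ge 0$.

### MC-PEM

`fit_mcpem()` implements importance-sampling Monte Carlo parametric EM.
The M-step is closed form: the log-scale population means move by the
average conditional mean of $\eta$, the diagonal $\omega^2$ update uses
the conditional second moments, and the residual parameter is updated
from the weighted residual sums. The E-step is where the work is. A
diagonal proposal is hopeless here: with up to eleven correlated random
effects per subject, importance weights degenerate (effective sample
sizes near 1) and the moment estimates they feed become noise — early
versions of the algorithm showed exactly this as runaway BSV estimates
for weakly identified parameters. The production E-step therefore uses
a full-covariance Gaussian proposal per subject: centred on the
conditional mode found by a warm-started quasi-Newton search, with a
Laplace covariance assembled from a batched finite-difference Hessian
(floored against the prior, marginal spreads capped at twice the prior
sd, mildly inflated), rebuilt whenever the subject's effective sample
size falls below `ess_floor` (default 2%) of the draws and refreshed
from the weighted posterior moments otherwise. Random-effect dimensions
a formulation cannot inform — the dissolution machinery of IR subjects —
keep the prior as proposal; their importance ratio is exactly one and
their conditional moments are entered analytically, which removes a
gratuitous source of Monte Carlo noise from the M-step.

Defaults are 1000 importance samples and 100 iterations. The marginal
likelihood estimate is tracked per iteration; under common random
numbers (`common_rng = TRUE`) it is non-decreasing up to Monte Carlo
tolerance, which the suite checks. $\omega^2$ updates are capped at 4
(log-scale variance) as a guard against the degenerate-weight feedback
described above.

### Two-stage cross-check

`fit_two_stage()` fits each subject by least squares on log
concentrations — the maximum-likelihood estimate under log-normal
residuals, agreeing with the proportional model to first order in the
CV — using repeated Nelder-Mead/quasi-Newton rounds on log parameters,
then pools log-scale means and variances. The log-scale objective is
deliberate: the concentrated proportional-error likelihood contains a
$\sum \log f$ term that rewards small predictions and created spurious
local minima in exactly the sum-of-exponentials directions this model
is sensitive to; the log-scale objective converges to the generating
values to ~1e-9 on noise-free data. Within a single oral profile the
bioavailability is confounded with the volume and clearance scale, so
`Frel_GR` is held at its initial value by default (the joint MC-PEM
fit, anchored by the IR arm, does estimate it). `Tlag` is also held: at
1.13 min it sits far below the first sample at 15 min and no
concentration datum can inform it.

### Standard errors

Standard errors come from a nonparametric bootstrap over subjects
(`bootstrap_se()`), which is robust at the study's n and agnostic to the
estimator. Because it multiplies the fitting cost by the number of
resamples, it is off by default and invoked explicitly.

## Synthetic studies

`generate_cohort()` emulates the parallel-group dog study the analysis
assumes: by default 5 subjects per arm, one 100 mg oral dose at time
zero, sampling at 0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 12,
24, 36 and 48 h, LLOQ 0.05 ug/mL, and multiplicative residual noise
$C(1+\varepsilon)$, $\varepsilon \sim N(0, CV^2)$ truncated at zero,
with CV 10% — inside the assay's stated precision envelope. One master
seed derives per-subject substreams that are logged in the truth record,
so cohorts are bit-reproducible. An SR (sustained-release tablet
without the floating device) arm has no mechanistic model of its own —
the observed SR kinetics are not explained by this model family — so SR
arms are generated only descriptively from user-supplied parameters and
documented as out-of-model.

What the generator deliberately does not emulate: food effects, gastric
pH and emptying physiology, vomiting or dropout, assay batch effects,
crossover designs (a crossover flag exists nowhere; the study is
parallel-group), and inter-occasion variability. Tests that pass on
these cohorts therefore certify the estimation machinery under the
model's own assumptions, not robustness to the many ways real dogs
violate them.

## Problem sizes used by the test suite

The suite exercises full-scale estimation once: a 50-subject virtual
study (25 IR + 25 GR) fitted with 1000 importance samples and 100 EM
iterations at a fixed seed, asserting recovery of the non-fixed
population means within 20%. `Tlag` is started at its reference value
in that study — data sampled from 15 min onwards cannot inform a 1-min
lag, and the check on it is that estimation leaves it in band rather
than that data recover it. The multi-seed recovery property (bias
within 20% and shrinking with n) runs on the fast two-stage probe at
cohort sizes of 20 and 60 across three seeds; module-level MC-PEM tests
use 8-12 subjects with a few hundred samples and a few dozen
iterations. The acceptance script refits a fresh 50-subject cohort at
400 samples and 50 iterations. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that a
maintainer will actually run.

## Known limitations

* The model family is the one described above; no covariates, no
  inter-occasion variability, single-dose designs only.
* At the reference design (17 samples, two arms of 25) the marginal
  likelihood is flat along ridges that trade the central volume, the
  absorption rates and the dissolution acceleration against each other:
  EM runs started from different initial values converge to different
  points on the ridge that fit the data equally well (identical
  residual CV). Population means along such ridges are reported as
  estimated but should not be over-interpreted to better than a few
  tens of percent without a richer design; the test suite documents
  this by checking which parameters a 50-subject study does and does
  not pin down.
* $\omega^2$ estimation for parameters the design barely informs
  (`Tlag`, and `V2`/`CLD` at small n) is noisy; the cap at 4 prevents
  divergence but is not a substitute for information.
* The importance-sampling E-step reports, via warnings, subjects whose
  effective sample size stays low; persistent warnings on real data
  signal a posterior the Gaussian proposal cannot cover and results
  should be treated accordingly.
* `linuplogdown` AUC and the additive residual model are implemented
  and tested, but the package's validated defaults are the linear
  trapezoid and the proportional model.
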