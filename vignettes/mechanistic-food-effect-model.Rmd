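---
title: "A mechanism-based model of food effects on fenofibrate absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanism-based model of food effects on fenofibrate absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenofood)
```

## The problem and the model

Fenofibrate is a lipid-lowering prodrug whose absorption is strongly
increased by food. After an oral sustained-release dose, the drug sits in
the stomach, empties slowly into the duodenum, and is there converted by
esterases to fenofibric acid — the active, measurable analyte — and
absorbed. Food intervenes three ways: a meal transiently accelerates
gastric emptying; calories arriving in the duodenum stimulate bile
secretion, which solubilises the lipophilic drug and speeds the combined
metabolism-absorption step; and overall bioavailability rises with food,
which a concentration-scale model sees as a drop in the apparent central
volume.

`fenofood` implements this as five coupled mass-balance ODEs, three for
drug amounts and two for calories:

$$
\begin{aligned}
dX_1/dt &= -k_g\,X_1 &
dX_4/dt &= -k_g'\,X_4\\
dX_2/dt &= k_g X_1 - k_{m\&a}\,(1 + E_{bile} X_5)\,X_2 &
dX_5/dt &= k_g' X_4 - k_{out}\,X_5\\
dX_3/dt &= k_{m\&a}(1 + E_{bile} X_5)X_2 - k_{el}\,X_3
\end{aligned}
$$

with $X_1, X_2, X_3$ the drug in stomach, duodenum and central
compartment (mg), and $X_4, X_5$ calories in stomach and duodenum.
Observed concentration is $C = X_3 / (V_c/F)$ in µg/mL.

Food enters through three covariate constructions:

* **Gastric-emptying window.** For a window after each meal,
  $k_g$ is multiplied by $(1+E_{food})$; the window is the half-open
  interval $[m_{t1}, m_{t2})$ after the meal (defaults 0 and 6.94 h),
  implemented as a change-point indicator and, numerically, as hard
  integration restarts at the boundaries.
* **Bile effect.** $k_{m\&a}$ scales linearly with the duodenal calorie
  amount $X_5$; the tested Michaelis–Menten alternative is deliberately
  out of scope — the linear form is the final model.
* **Food-type volume effect.** $V_c/F$ is multiplied by $(1+E_{Vc1})$
  (standard meal) or $(1+E_{Vc2})$ (high-fat meal). Because distribution
  itself is not changed by a meal, the volume drop is read as a
  bioavailability gain: $F$-fold $= 1/(1+E_{Vc})$.

Between-subject variability is log-normal on the gastric-emptying rate
(one deviate shared by $k_g$ and $k_g'$), $k_{el}$ and $V_c/F$;
between-occasion variability on the latter two; residual error is
proportional.

### Calorie units

The state variables $X_4, X_5$ carry calories in units of 100 kcal
(`calorie_unit_kcal`, configurable). Only this scaling makes the default
$E_{bile} = 0.0239$ reproduce the published fed absorption rates
(0.198 × (1 + 0.0239 × 6.863) ≈ 0.23 h⁻¹ for a 686.3 kcal meal); the
unit is not stated anywhere in the source material.

### Parameters and defaults

`mbpk_params()` carries the full default set: $k_g$ 0.0412 h⁻¹,
$k_{m\&a}$ 0.198 h⁻¹, $k_{el}$ 0.27 h⁻¹, $V_c/F$ 12.9 L, $k_g'$
0.00971 h⁻¹, $k_{out}$ 0.00972 h⁻¹, $E_{bile}$ 0.0239 per 100 kcal,
$E_{food}$ 0.617, $E_{Vc1}$ −0.394, $E_{Vc2}$ −0.461, window end 6.94 h,
proportional residual SD 0.608. Printed %CVs are read directly as
100·ω (ω\_kg 0.317, ω\_kel 0.863, ω\_Vc 0.93; IOV π\_kel 0.449, π\_Vc
0.509); `cv_to_omega(cv, "lognormal")` provides the alternative
$\omega = \sqrt{\ln(1+CV^2)}$ convention. The IOV magnitudes follow the
estimates table, whose rows disagree with the accompanying text (which
swaps the two values). The physiological stomach/duodenum volumes
(0.049/1/0.045 L) are stored as metadata only: the model equations are
written on amounts, so these volumes cancel and play no computational
role.

```{r}
derived_fed_parameters(mbpk_params(), 686.3, "standard")
```

## Numerics

The ODE system is linear with piecewise-constant (window) and smooth
($X_5$-driven) time variation and rate constants all ≤ 0.27 h⁻¹ — it is
not stiff. The integrator is an adaptive embedded Dormand–Prince 5(4)
pair written in C++ (rtol 1e-8, atol 1e-10 by default) that restarts at
every dose, meal and window boundary so no discontinuity is stepped
across. Speed was the design driver: a population fit evaluates on the
order of 10⁵–10⁶ profiles. Correctness is established against two
independent oracles in the test-suite: the closed-form three-exponential
cascade (fasted conditions; `cascade_conc()`), and `deSolve::lsoda` on a
fed profile integrated piecewise across the window boundary. The calorie
subsystem has its own closed form (`calorie_kinetics()`) including the
confluent equal-rate limit, used when $|k_{out}-k_g'| < 10^{-8}$ — the
default values (0.00971 vs 0.00972) are deliberately *not* collapsed to
the limit.

Mass balance is tracked explicitly: the state vector carries cumulative
drug and calorie elimination, and the tests require
$X_1+X_2+X_3+\int k_{el}X_3 = \text{dose}$ to integrator tolerance.

## Estimation

`fit_mbpk()` maximises an FOCE-I-style approximate marginal likelihood:
for each subject the penalised conditional −2 log density is minimised
over the subject's random effects (a damped Gauss–Newton iteration with
exact gradients from the prediction Jacobian, falling back to a generic
quasi-Newton search), and the subject's objective contribution is the
Laplace value with the curvature taken as the Gauss–Newton (linearised)
Hessian $J^\top W J + \Omega^{-1}$ — the standard FOCE-I form, with $W$
evaluated at the conditional predictions (the "interaction"). All
$2\pi$ constants are included, so the objective function value (OFV) is
an honest −2 log likelihood approximation; it reduces exactly to the
closed-form marginal likelihood in the linear-Gaussian special case
(verified at 1e-4 in the tests) and to the naive-pooled −2LL when all
variability terms are zero.

The outer optimisation runs on unconstrained scales — log for rates,
volumes, window end and variability terms; shifted log $\log(1+x)$ for
$E_{food}$ and $E_{bile}$ (support $>-1$); a scaled logit on $(-1, 10)$
for the volume coefficients — with a central finite-difference gradient
whose step (5e-4) is chosen to sit above the small warm-start hysteresis
of the inner Laplace step, and with automatic restarts when the
quasi-Newton search reports false convergence. Inner tolerance is 1e-9,
outer relative tolerance 1e-6. Standard errors come from the
finite-difference Hessian of the OFV with a delta-method transform back
to the natural scale; RSE% = 100·SE/|estimate|.

Random effects with ω (or π) set exactly to zero are treated as absent,
which gives the degenerate limits their natural meaning. Under additive
error, an uninformative likelihood (σ → ∞) shrinks every empirical Bayes
estimate to zero; under proportional error that classical statement
fails, because the log-variance term keeps depending on the predictions
through the interaction — the shrinkage property is therefore stated and
tested under additive error. The same interaction term gives a
proportional-error ML fit of noise-free data a small $O(\sigma^2)$
downward prediction bias, which is why the "residuals vanish on
noiseless data" check is run under additive error as well.

### Identifiability at this design

Two structural facts shape every estimation experiment on this model:

* **Rate-exchange symmetry.** Under fasted conditions the drug chain is
  a three-stage catenary cascade, and its output is invariant under
  exchanging $k_{m\&a}$ and $k_{el}$ with a compensating volume rescale
  $V_c' = V_c\,k_{m\&a}/k_{el}$. The two branches are distinguished
  pharmacologically (fenofibric acid's elimination is faster than the
  sustained-release absorption cascade), not statistically; fits must be
  started on the correct ordering $k_{m\&a} < k_{el}$.
* **The bile coefficient is barely identifiable from 72-h data.** With
  $k_g' \approx k_{out} \approx 0.0097$ h⁻¹, the duodenal calorie load
  $X_5(t) \approx k_g' X_{4,0}\, t\, e^{-k_g' t}$ peaks around $t = 103$
  h — after the last sample. Within 72 h, $X_5$ reaches only ~2.4 units
  (686.3 kcal) or ~4.4 units (1280 kcal), perturbing $k_{m\&a}$ by at
  most 6–11%, far below the 60.8% proportional residual noise. In
  simulation-estimation experiments $E_{bile}$ therefore wanders (its
  sampling distribution easily spans zero) and drags $k_{m\&a}$ and
  $k_{el}$ with it. The package's parameter-recovery experiments hold
  $E_{bile}$ at its generating value for this reason; its dynamic effect
  remains in the simulated data. The fed-state *reporting* convention
  (`derived_fed_parameters()`) evaluates the bile effect at the full
  meal-calorie load — a convention for expressing the coefficient on the
  scale of the printed meal sizes, distinct from the dynamic $X_5(t)$
  the ODE uses, which never reaches that load.

The recovery experiment shipped in the test-suite simulates the full
crossover (24 subjects × 3 periods, default parameters, fixed seed),
then refits the four main fixed effects, the three food coefficients
($E_{food}$, $E_{Vc1}$, $E_{Vc2}$), the three ω's and σ from a
deliberately displaced start, holding $k_g'$, $k_{out}$, the window end
and the two IOV π's fixed (the π's to keep the experiment inside a
test-suite-friendly compute budget). Gates: main fixed effects within
30%, ω's within 50%. With ~20% log-scale asymptotic SE on $k_{el}$ at
this design, the 30% gate sits at about 1.5 SE — adequate for a smoke
test of estimator sanity, but individual parameters can land near the
boundary by ordinary sampling variation.

## The synthetic-trial generator

`generate_trial()` emulates the statistical structure of the study the
model was developed on: 24 healthy subjects in a three-way crossover
(fasted / 686.3 kcal standard / high-fat meal, the last defaulting to
the printed 1280 kcal meal, configurable to the 908 kcal used in
derived-parameter reporting), a single 250 mg sustained-release dose
taken with the period meal, samples at 1, 2, 3, 4, 5, 6, 8, 10, 12, 24,
48 and 72 h, and a flagged pre-dose zero sample. Periods are simulated
independently — a 168-h washout (unstated in the source; chosen as
standard single-dose crossover practice, > 9 terminal half-lives of the
slowest process within each period's drug amounts) only lays out the
cumulative time axis. The meal and dose share the clock time: the actual
10-minute gap is negligible against an emptying half-life of ~17 h.
Negative concentrations after applying proportional error are redrawn
(rejection) rather than truncated, keeping the error CV interpretable;
at the default σ this clips the lower tail beyond −1/σ ≈ −1.64 SD, so
the realised observation-level CV is ≈ 0.55 rather than 0.608, a
documented property of the generator. What the generator deliberately
does *not* emulate: demographic covariates (no role in the final model),
carryover, dropout, or assay quantification limits — so green tests here
certify the estimator and diagnostics on the assumed data-generating
process, not robustness to real-data pathologies.

Two frozen fixtures ship in `inst/extdata/` (6 and 24 subjects, seeds
101 and 202, recorded in the file headers); `scripts/make_fixtures.R`
regenerates them byte-identically.

## Simulation and exposure

`simulate_cohort()` reproduces the multiple-dose food-effect scenarios:
250 mg once daily for 7 days (doses at 0, 24, …, 144 h), each dose with
its group's meal, n individuals with fresh inter-individual deviates and
a single occasion (IOV drawn once — occasion structure in a
multiple-dose regimen is a design choice, configurable through
`sample_random_effects()`). Exposure is summarised on residual-error-free
individual predictions over the final dosing interval at steady state
([144, 168] h): $C_{max}^{ss}$ as the maximum on a 0.25-h grid (location
error bounded by the grid; the profile's curvature at its flat post-dose
maximum makes the value error ≪ 0.1%), and AUC by the trapezoidal rule
on the same grid. Mean, SE and median are reported.

Reproducing the published steady-state exposure table deserves honesty:
under the printed variability magnitudes (ω\_Vc = 0.93, ω\_kel = 0.863
log-scale), individual exposures are heavily right-skewed lognormals,
and the arithmetic cohort mean of $C_{max}^{ss}$ at n = 1000 is ≈ 10
µg/mL for the fasted group — not the published 3.17 ± 0.07. No %CV→ω
convention brings the arithmetic mean close. The cohort *median* under
the direct convention is ≈ 3.2 µg/mL, matching the published value, and
the published SE implies a far lighter-tailed summary than the printed
random-effect model's mean; separately, the published AUC over the 24-h
window equals 100 × the published $C_{max}$ in all three groups, which
no 24-h integral of these profiles can satisfy. The package therefore
reports mean, SE and median, and the corresponding acceptance check is
kept at the published face values and allowed to fail, rather than
silently redefining the summary statistic. (The exposure window itself
is the final dosing interval; the published window label is ambiguous
between "the 24 h after the last dose" and "the last dosing interval",
which are time-translations of one another at steady state.)

```{r}
cs <- simulate_cohort(sim_scenario("fasted"), mbpk_params(), n = 50,
                      seed = 1)
cs$summary
```

## Diagnostics

* `residual_table()` gives PRED (population prediction), IPRED
  (at the empirical Bayes estimates) and CWRES — residuals decorrelated
  by the lower-Cholesky factor of the FOCE-linearised marginal
  covariance $J\Omega J^\top + \mathrm{diag}(\sigma^2 f^2)$ about the
  conditional mode. For a correctly specified model they are near
  standard normal (tested: mean within ±0.1, variance in [0.8, 1.2] at
  500+ observations).
* `vpc()` simulates replicate datasets at the exact design of the input
  (same subjects, occasions, doses, meals, times), stratifies by food
  type, bins at the nominal sampling times (the design is fixed-time;
  break-point binning is available for irregular designs) and wraps the
  2.5–97.5% band across replicates around each tracked percentile.
  Self-calibration — data simulated from the model should be covered in
  ≥ 90% of bins — is part of the acceptance tests.
* `mbpk_bootstrap()` implements the 90% *subsample* (without
  replacement) flavour used to validate the original analysis — chosen
  deliberately over the classical resample-with-replacement bootstrap,
  which is available via `replace = TRUE`; subsampling avoids duplicated
  subjects (awkward in nonlinear mixed models) at the price of slightly
  conservative intervals.

## Problem sizes used in the shipped experiments

The test-suite and acceptance script run: the full 24 × 3 recovery fit
(one seed, ~5 min), a 1000-individual fasted cohort (seconds), a
200-replicate VPC on a 24-subject trial, and small (≤ 6 subject)
bootstrap and noiseless-recovery fits. These sizes were chosen as the
smallest that exercise each claim at its stated tolerance.

## Known limitations

* $E_{bile}$ is reported with the model but should not be expected to be
  recoverable from 72-h single-dose data (see above); its default is the
  published estimate, not something this package can re-derive.
* FOCE-I is an approximation; no SAEM/adaptive Gaussian quadrature
  alternative is provided, and Ω is diagonal by construction.
* The integrator is non-stiff by design; pathological parameter sets
  (rates orders of magnitude above the defaults) would want a stiff
  method.
* Exposure summaries use grid-based maxima, not root-finding; the
  0.25 h default grid bounds the $C_{max}$ location error accordingly.
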