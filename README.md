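# fenofood

Mechanism-based population pharmacokinetics of food effects on
fenofibrate absorption.

## What this is for

Fenofibrate, an oral lipid-lowering prodrug given as a sustained-release
capsule, is absorbed much better with food. `fenofood` is an R package
for pharmacometricians who want to simulate, fit and evaluate a
mechanistic gastrointestinal model of that food effect, in which meals
act through physiology rather than as a categorical covariate: a
transient post-meal boost of gastric emptying, a bile-mediated
calorie-driven increase of the metabolism/absorption rate, and a
food-type-dependent gain in bioavailability.

The model is a five-state ODE system for amounts of drug
(stomach, duodenum, central fenofibric acid) and calories (stomach,
duodenum):

    dX1/dt = -kg * X1
    dX2/dt =  kg * X1 - kma * (1 + Ebile * X5) * X2
    dX3/dt =  kma * (1 + Ebile * X5) * X2 - kel * X3
    dX4/dt = -kg' * X4
    dX5/dt =  kg' * X4 - kout * X5

with concentration `C = X3 / (Vc/F)` (µg/mL), `kg` multiplied by
`(1 + Efood)` inside a change-point window after each meal, `X4`/`X5` in
100-kcal units, and `Vc/F` scaled by `(1 + EVc1)` or `(1 + EVc2)` under
a standard or high-fat meal (`fold bioavailability = 1/(1 + EVc)`).
Inter-individual and inter-occasion variability are log-normal; residual
error is proportional. Estimation is FOCE-I-style (per-subject Laplace
with interaction, Gauss–Newton curvature).

The package provides:

* `mbpk_params()`, `event_schedule()`, `solve_profile()` — the model and
  a fast compiled event-aware ODE solver, plus closed-form oracles
  (`cascade_conc()`, `calorie_kinetics()`);
* `derived_fed_parameters()` — fed-state parameter and bioavailability
  reporting;
* `sample_random_effects()`, `simulate_cohort()`,
  `run_scenario_report()` — population simulation and steady-state
  exposure (C_max, AUC over the final dosing interval);
* `generate_trial()` — a synthetic three-way crossover generator
  (24 subjects, fasted / standard / high-fat periods, 250 mg single
  dose, 72-h sampling) standing in for the study's raw clinical data;
* `fit_mbpk()`, `foce_objective()`, `conditional_estimates()` —
  nonlinear mixed-effects estimation;
* `residual_table()`, `vpc()`, `mbpk_bootstrap()` — CWRES diagnostics,
  visual predictive checks, and 90%-subsample bootstrap;
* `read_pk_dataset()` / `write_pk_dataset()` — a NONMEM-style delimited
  dataset dialect (`ID, TIME, AMT, DV, EVID, MDV, OCC, FOOD, CAL`).

## Worked example

```r
library(fenofood)
p <- mbpk_params()          # published estimates as defaults

# fed-state derived parameters for a 686.3 kcal standard meal
derived_fed_parameters(p, 686.3, "standard")
#>               quantity     value  fasted percent_change units
#> 1               kg_fed 0.0666204  0.0412       61.70000   1/h
#> 2              kma_fed 0.2304771  0.1980       16.40257   1/h
#> 3               vc_fed 7.8174000 12.9000      -39.40000     L
#> 4 bioavailability_fold 1.6501650  1.0000       65.01650  fold
```

Gastric emptying is 61.7% faster for 6.94 h after the meal, the
absorption rate rises to 0.23 h⁻¹ at the full meal-calorie load, and the
apparent volume drops to 7.82 L — i.e. bioavailability rises 1.65-fold.

```r
# typical single-dose profile, 250 mg with the standard breakfast
sch <- event_schedule(0, 250, meal_times = 0, meal_calories = 686.3,
                      food_type = "standard")
solve_profile(p, sch, t_grid = c(1, 4, 8, 12, 24, 48, 72))
#>   time   conc
#> 1    1 0.1768
#> 2    4 1.6843
#> 3    8 3.4102
#> 4   12 3.6067
#> 5   24 2.3110
#> 6   48 0.8390
#> 7   72 0.3104
```

Concentrations (µg/mL fenofibric acid) peak around 12 h — absorption is
rate-limited by the slow gastric emptying of the sustained-release
formulation.

```r
# steady-state exposure, fasted group, 250 mg once daily x 7 days
simulate_cohort(sim_scenario("fasted"), p, n = 200, seed = 7)
#> Cohort simulation: fasted, 0 kcal, 250 mg x 7 days (n = 200, seed 7)
#> Exposure window: [144, 168] h
#>  metric    mean      se median   units
#>    cmax   7.949  0.7922  3.666   ug/mL
#>     auc 175.855 18.0290 79.108 ug*h/mL
```

The mean/median gap reflects the strongly right-skewed log-normal
inter-individual variability (ω on Vc/F of 0.93); see the methods
vignette (`vignettes/mechanistic-food-effect-model.Rmd`) for why both
are reported and how they relate to previously published summaries.

A full simulation-estimation round trip:

```r
trial <- generate_trial(trial_design(), mbpk_params(), seed = 202)
fit <- fit_mbpk(trial$dataset, start = mbpk_params())
fit$estimates   # compare against trial$truth
vpc(trial$dataset, fit$params, n_replicates = 200, seed = 1)
```

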