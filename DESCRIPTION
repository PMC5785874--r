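Package: fenofood
Title: Mechanism-Based Population Pharmacokinetics of Fenofibrate Food Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, nonlinear mixed-effects (FOCE-I style)
    estimation and diagnostics for a mechanism-based gastrointestinal
    absorption model of fenofibrate. The model couples a five-state
    ordinary-differential-equation system (drug in stomach, duodenum and a
    central fenofibric-acid compartment; meal calories in stomach and
    duodenum) with a post-meal gastric-emptying window, a calorie-driven
    bile effect on the combined metabolism-absorption rate, and food-type
    effects on the apparent central volume. Includes a synthetic three-way
    crossover trial generator, visual predictive checks, subsample
    bootstrap uncertainty, and steady-state exposure simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
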