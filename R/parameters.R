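#' Model parameters for the mechanism-based food-effect model
#'
#' Constructs the full parameter set of the gastrointestinal absorption
#' model: fixed effects, food-effect coefficients, change-point window
#' times, inter-individual (IIV) and inter-occasion (IOV) variability and
#' the proportional residual error. Defaults are the published estimates
#' for a 250 mg sustained-release fenofibrate capsule, with fenofibric
#' acid as the observed analyte.
#'
#' Random-effect magnitudes are stored as standard deviations on the log
#' scale. The printed coefficients of variation are converted with
#' [cv_to_omega()]; the default reads \%CV directly as `100 * omega`
#' (the usual reporting convention for exponential random-effect models).
#'
#' @param tv_kg Typical fasted gastric-emptying rate constant of drug (1/h).
#' @param k_ma Combined metabolism + absorption rate constant (1/h).
#' @param k_el Elimination rate constant of fenofibric acid (1/h).
#' @param vc_over_f Apparent central volume of distribution Vc/F (L).
#' @param kg_prime Gastric-emptying rate constant of calories (1/h).
#' @param k_out Calorie elimination rate constant from the duodenum (1/h).
#' @param e_bile Bile-effect coefficient on `k_ma` per calorie unit
#'   (dimensionless per `calorie_unit_kcal` kcal in the duodenum).
#' @param e_food Fractional increase of the gastric-emptying rate while the
#'   post-meal food window is active (dimensionless).
#' @param e_vc1,e_vc2 Fractional change of Vc/F for a standard and a
#'   high-fat meal (dimensionless, greater than -1).
#' @param mtime1,mtime2 Food-window start and end, hours after the meal.
#' @param v_stomach_fasted,v_stomach_fed,v_duodenum Fixed physiological
#'   volumes (L). Metadata only: the model equations are written on
#'   amounts, so these volumes cancel and never enter a computation.
#' @param omega_kg,omega_kel,omega_vc IIV standard deviations (log scale)
#'   for the gastric-emptying rate (shared between drug and calories),
#'   `k_el` and Vc/F.
#' @param pi_kel,pi_vc IOV standard deviations (log scale) for `k_el` and
#'   Vc/F.
#' @param sigma_prop Proportional residual error standard deviation.
#' @param calorie_unit_kcal Size of one internal calorie unit in kcal.
#'   The bile coefficient is expressed per this unit; the default of 100
#'   kcal is the only scaling under which the published `e_bile`
#'   reproduces the published fed absorption rates.
#'
#' @return An object of class `mbpk_params` (a validated named list).
#' @examples
#' p <- mbpk_params()
#' p$tv_kg
#' mbpk_params(e_food = 0) # switch the gastric-emptying boost off
#' @export
mbpk_params <- function(tv_kg = 0.0412,
                        k_ma = 0.198,
                        k_el = 0.27,
                        vc_over_f = 12.9,
                        kg_prime = 0.00971,
                        k_out = 0.00972,
                        e_bile = 0.0239,
                        e_food = 0.617,
                        e_vc1 = -0.394,
                        e_vc2 = -0.461,
                        mtime1 = 0,
                        mtime2 = 6.94,
                        v_stomach_fasted = 0.049,
                        v_stomach_fed = 1,
                        v_duodenum = 0.045,
                        omega_kg = cv_to_omega(31.7),
                        omega_kel = cv_to_omega(86.3),
                        omega_vc = cv_to_omega(93),
                        pi_kel = cv_to_omega(44.9),
                        pi_vc = cv_to_omega(50.9),
                        sigma_prop = 0.608,
                        calorie_unit_kcal = 100) {
  p <- list(
    tv_kg = tv_kg, k_ma = k_ma, k_el = k_el, vc_over_f = vc_over_f,
    kg_prime = kg_prime, k_out = k_out, e_bile = e_bile, e_food = e_food,
    e_vc1 = e_vc1, e_vc2 = e_vc2, mtime1 = mtime1, mtime2 = mtime2,
    v_stomach_fasted = v_stomach_fasted, v_stomach_fed = v_stomach_fed,
    v_duodenum = v_duodenum,
    omega_kg = omega_kg, omega_kel = omega_kel, omega_vc = omega_vc,
    pi_kel = pi_kel, pi_vc = pi_vc, sigma_prop = sigma_prop,
    calorie_unit_kcal = calorie_unit_kcal
  )
  p <- lapply(p, function(x) {
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
    as.numeric(x)
  })
  class(p) <- "mbpk_params"
  validate_mbpk_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model: strictly positive rate
#' constants, volumes and residual error; volume and emptying effects that
#' keep their targets positive (`e_vc > -1`, `e_food > -1`); non-negative
#' variability terms; and an ordered food window (`mtime2 > mtime1 >= 0`).
#'
#' @param p An `mbpk_params` object (or plain named list with the same
#'   fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_mbpk_params <- function(p) {
  pos <- c("tv_kg", "k_ma", "k_el", "vc_over_f", "kg_prime", "k_out",
           "sigma_prop", "v_stomach_fasted", "v_stomach_fed", "v_duodenum",
           "calorie_unit_kcal")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$sigma_prop < 0) stop("'sigma_prop' must be positive", call. = FALSE)
  for (nm in c("omega_kg", "omega_kel", "omega_vc", "pi_kel", "pi_vc")) {
    if (p[[nm]] < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$e_vc1 <= -1 || p$e_vc2 <= -1)
    stop("'e_vc1' and 'e_vc2' must exceed -1 (Vc/F stays positive)", call. = FALSE)
  if (p$e_food <= -1)
    stop("'e_food' must exceed -1 (gastric emptying stays positive)", call. = FALSE)
  if (p$mtime1 < 0) stop("'mtime1' must be >= 0", call. = FALSE)
  if (p$mtime2 <= p$mtime1) stop("'mtime2' must exceed 'mtime1'", call. = FALSE)
  invisible(p)
}

#' Convert a printed coefficient of variation to a log-scale SD
#'
#' Exponential random-effect models report variability as a coefficient of
#' variation. Two conventions circulate: reading \%CV directly as
#' `100 * omega` (`"direct"`, the common reporting shortcut, exact for
#' small CV), and the lognormal identity `omega = sqrt(log(1 + CV^2))`
#' (`"lognormal"`).
#'
#' @param cv_percent Coefficient of variation in percent.
#' @param method `"direct"` (default) or `"lognormal"`.
#' @return Log-scale standard deviation.
#' @examples
#' cv_to_omega(31.7)
#' cv_to_omega(93, method = "lognormal")
#' @export
cv_to_omega <- function(cv_percent, method = c("direct", "lognormal")) {
  method <- match.arg(method)
  stopifnot(is.numeric(cv_percent), all(cv_percent >= 0))
  cv <- cv_percent / 100
  switch(method,
    direct = cv,
    lognormal = sqrt(log(1 + cv^2))
  )
}

#' @export
print.mbpk_params <- function(x, ...) {
  cat("Mechanism-based food-effect PK parameters\n")
  cat(sprintf("  fixed effects : kg %.4g  k_ma %.4g  k_el %.4g  Vc/F %.4g L\n",
              x$tv_kg, x$k_ma, x$k_el, x$vc_over_f))
  cat(sprintf("  calories      : kg' %.4g  k_out %.4g  (unit %g kcal)\n",
              x$kg_prime, x$k_out, x$calorie_unit_kcal))
  cat(sprintf("  food effects  : E_food %.3g on kg in [%g, %g) h; E_bile %.3g /unit\n",
              x$e_food, x$mtime1, x$mtime2, x$e_bile))
  cat(sprintf("                  E_Vc1 %.3g (standard)  E_Vc2 %.3g (high fat)\n",
              x$e_vc1, x$e_vc2))
  cat(sprintf("  IIV (omega)   : kg %.3g  k_el %.3g  Vc %.3g\n",
              x$omega_kg, x$omega_kel, x$omega_vc))
  cat(sprintf("  IOV (pi)      : k_el %.3g  Vc %.3g\n", x$pi_kel, x$pi_vc))
  cat(sprintf("  residual      : proportional SD %.3g\n", x$sigma_prop))
  invisible(x)
}

#' Read / write a parameter set as a flat YAML file
#'
#' The file holds one key per parameter field, so a parameter set can be
#' versioned alongside an analysis. A defaults file with the published
#' estimates ships with the package (see the example).
#'
#' @param path File path.
#' @param p An `mbpk_params` object.
#' @return `read_mbpk_params()` returns an `mbpk_params` object;
#'   `write_mbpk_params()` returns `path` invisibly.
#' @examples
#' p <- read_mbpk_params(system.file("extdata", "default_parameters.yaml",
#'                                   package = "fenofood"))
#' @export
read_mbpk_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mbpk_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(mbpk_params, vals)
}

#' @rdname read_mbpk_params
#' @export
write_mbpk_params <- function(p, path) {
  stopifnot(inherits(p, "mbpk_params"))
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

# Update selected fields of a parameter set, re-validating.
#' Modify a parameter set
#'
#' @param p An `mbpk_params` object.
#' @param ... Named fields to replace.
#' @return A new validated `mbpk_params` object.
#' @examples
#' update_mbpk_params(mbpk_params(), e_bile = 0, e_food = 0)
#' @export
update_mbpk_params <- function(p, ...) {
  stopifnot(inherits(p, "mbpk_params"))
  do.call(mbpk_params, utils::modifyList(unclass(p), list(...)))
}
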