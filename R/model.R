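#' Post-meal food window indicator
#'
#' The gastric-emptying boost is active on the half-open window
#' `[meal_time + mtime1, meal_time + mtime2)` and only under fed
#' conditions; it is the change-point ("past-time") construction used to
#' switch a rate parameter on and off around an event.
#'
#' @param t Evaluation time(s), h (>= 0).
#' @param meal_time Meal time, h.
#' @param mtime1,mtime2 Window start and end relative to the meal, h
#'   (`mtime2 > mtime1`).
#' @param fed Logical; `FALSE` forces the indicator to zero at all times.
#' @return Integer vector of 0/1, same length as `t`.
#' @examples
#' food_window_indicator(c(3, 8), meal_time = 0, mtime1 = 0, mtime2 = 6.94,
#'                       fed = TRUE)
#' @export
food_window_indicator <- function(t, meal_time, mtime1, mtime2, fed) {
  stopifnot(mtime2 > mtime1, is.logical(fed), length(fed) == 1L)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (!fed) return(integer(length(t)))
  as.integer(t >= meal_time + mtime1 & t < meal_time + mtime2)
}

#' Effective gastric-emptying rate of drug
#'
#' `tv_kg * (1 + e_food)^indicator`: the fasted rate outside the food
#' window, boosted by the fractional food effect inside it.
#'
#' @param tv_kg Typical fasted gastric-emptying rate (1/h, > 0).
#' @param e_food Fractional food effect (> -1).
#' @param indicator 0/1 window indicator (vectorised).
#' @return Rate constant(s), 1/h.
#' @examples
#' effective_kg(0.0412, 0.617, 1) # boosted post-meal rate
#' @export
effective_kg <- function(tv_kg, e_food, indicator) {
  stopifnot(all(tv_kg > 0), all(indicator %in% c(0, 1)))
  if (any(e_food <= -1)) stop("'e_food' must exceed -1", call. = FALSE)
  tv_kg * (1 + e_food)^indicator
}

#' Effective metabolism + absorption rate
#'
#' The combined fenofibrate-to-fenofibric-acid conversion and absorption
#' rate scales linearly with the calorie load in the duodenum through the
#' bile effect: `k_ma * (1 + e_bile * x5)`.
#'
#' @param k_ma Fasted combined rate constant (1/h, > 0).
#' @param e_bile Bile coefficient per calorie unit.
#' @param x5 Calories in the duodenum (calorie units, >= 0; vectorised).
#' @return Rate constant(s), 1/h; errors if any value would be <= 0.
#' @examples
#' effective_kma(0.198, 0.0239, 6.863) # 686.3 kcal in 100-kcal units
#' @export
effective_kma <- function(k_ma, e_bile, x5) {
  stopifnot(all(k_ma > 0), all(x5 >= 0))
  out <- k_ma * (1 + e_bile * x5)
  if (any(out <= 0))
    stop("effective k_ma must stay positive (e_bile too negative for x5)",
         call. = FALSE)
  out
}

#' Effective apparent central volume
#'
#' Fasted Vc/F, scaled by `(1 + e_vc1)` under a standard meal and
#' `(1 + e_vc2)` under a high-fat meal. The decrease in apparent volume
#' encodes the increase in bioavailability F.
#'
#' @param vc_over_f Fasted apparent central volume (L, > 0).
#' @param food_type One of [FOOD_TYPES].
#' @param e_vc1,e_vc2 Fractional volume effects (> -1).
#' @return Volume (L).
#' @examples
#' effective_vc(12.9, "standard")
#' effective_vc(12.9, "high_fat")
#' @export
effective_vc <- function(vc_over_f, food_type, e_vc1 = -0.394,
                         e_vc2 = -0.461) {
  stopifnot(vc_over_f > 0, e_vc1 > -1, e_vc2 > -1)
  food_type <- match.arg(food_type, FOOD_TYPES)
  out <- switch(food_type,
    fasted = vc_over_f,
    standard = vc_over_f * (1 + e_vc1),
    high_fat = vc_over_f * (1 + e_vc2)
  )
  out
}

#' Right-hand side of the five-state absorption model
#'
#' Pure-R reference implementation of the coupled drug/calorie system:
#' drug transits stomach -> duodenum -> central compartment with the
#' window-boosted emptying rate and the bile-modulated combined
#' metabolism-absorption rate; calories transit stomach -> duodenum ->
#' out. Used for documentation, finite-difference checks and as the
#' right-hand side for external integrators; production solves go through
#' the compiled integrator in [solve_profile()].
#'
#' @param state Numeric vector `c(x1, x2, x3, x4, x5)`: drug in stomach,
#'   duodenum and central compartment (mg) and calories in stomach and
#'   duodenum (calorie units).
#' @param t Time (h).
#' @param params An `mbpk_params` object.
#' @param schedule An `event_schedule` (supplies meal times and food type
#'   for the window indicator).
#' @return Numeric vector of derivatives, same order as `state`.
#' @examples
#' p <- mbpk_params()
#' sch <- event_schedule(0, 250)
#' ode_rhs(c(250, 0, 0, 0, 0), 0, p, sch)
#' @export
ode_rhs <- function(state, t, params, schedule) {
  stopifnot(length(state) == 5L, inherits(schedule, "event_schedule"))
  fed <- schedule$food_type != "fasted"
  ind <- 0L
  if (fed && length(schedule$meal_times) > 0) {
    ind <- max(vapply(
      schedule$meal_times,
      function(mt) food_window_indicator(t, mt, params$mtime1, params$mtime2,
                                         fed = TRUE),
      integer(1)
    ))
  }
  kg <- effective_kg(params$tv_kg, params$e_food, ind)
  kma <- effective_kma(params$k_ma, params$e_bile, state[4 + 1])
  c(
    -kg * state[1],
    kg * state[1] - kma * state[2],
    kma * state[2] - params$k_el * state[3],
    -params$kg_prime * state[4],
    params$kg_prime * state[4] - params$k_out * state[5]
  )
}

# Internal: food windows implied by a schedule, as a 2-column matrix.
schedule_windows <- function(schedule, params) {
  if (schedule$food_type == "fasted" || length(schedule$meal_times) == 0)
    return(matrix(numeric(0), ncol = 2))
  cbind(schedule$meal_times + params$mtime1,
        schedule$meal_times + params$mtime2)
}

#' Solve an individual concentration-time profile
#'
#' Integrates the five-state system for one subject-occasion with an
#' adaptive embedded Runge-Kutta method, restarting the integration at
#' every dose, meal and food-window boundary so the discontinuities are
#' resolved exactly. Doses are added to the drug stomach compartment and
#' meal calories (converted to calorie units) to the calorie stomach
#' compartment at their event times. The fenofibric-acid concentration is
#' the central amount divided by the food-type-adjusted apparent volume
#' (mg/L, numerically equal to ug/mL).
#'
#' @param params An `mbpk_params` object (typical values).
#' @param schedule An `event_schedule`.
#' @param t_grid Output times (h, sorted, >= 0).
#' @param eta Named IIV deviates `c(kg = , kel = , vc = )` on the log
#'   scale; the gastric-emptying deviate is shared between drug and
#'   calorie emptying rates.
#' @param kappa Named IOV deviates `c(kel = , vc = )` for this occasion.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @return A data.frame with columns `time` and `conc`, with attributes
#'   `states` (matrix of the five state variables plus cumulative drug and
#'   calorie elimination at `t_grid`) and `vc_eff` (the occasion's
#'   apparent volume, L).
#' @examples
#' prof <- solve_profile(mbpk_params(), event_schedule(0, 250),
#'                       t_grid = c(1, 4, 12, 24, 72))
#' prof$conc
#' @export
solve_profile <- function(params, schedule, t_grid,
                          eta = c(kg = 0, kel = 0, vc = 0),
                          kappa = c(kel = 0, vc = 0),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "mbpk_params"),
            inherits(schedule, "event_schedule"))
  t_grid <- as.numeric(t_grid)
  if (any(t_grid < 0) || is.unsorted(t_grid))
    stop("'t_grid' must be sorted and non-negative", call. = FALSE)
  eta <- eta_full(eta)
  kappa <- kappa_full(kappa)

  kg_i <- params$tv_kg * exp(eta[["kg"]])
  kgp_i <- params$kg_prime * exp(eta[["kg"]])  # shared IIV with drug emptying
  kel_i <- params$k_el * exp(eta[["kel"]] + kappa[["kel"]])
  vc_i <- effective_vc(params$vc_over_f, schedule$food_type,
                       params$e_vc1, params$e_vc2) *
    exp(eta[["vc"]] + kappa[["vc"]])

  doses <- cbind(schedule$dose_times, schedule$dose_amounts)
  meals <- cbind(schedule$meal_times,
                 schedule$meal_calories / params$calorie_unit_kcal)
  if (nrow(meals) == 0) meals <- matrix(numeric(0), ncol = 2)
  windows <- schedule_windows(schedule, params)

  states <- tryCatch(
    .mbpk_solve_cpp(numeric(7), t_grid, kg_i, params$e_food, params$k_ma,
                    params$e_bile, kel_i, kgp_i, params$k_out,
                    doses, meals, windows, rtol, atol),
    error = function(e) {
      stop("profile integration failed (food type ", schedule$food_type,
           ", ", length(schedule$dose_times), " dose(s)): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  colnames(states) <- c("x1", "x2", "x3", "x4", "x5",
                        "drug_eliminated", "cal_eliminated")
  out <- data.frame(time = t_grid, conc = states[, "x3"] / vc_i)
  attr(out, "states") <- states
  attr(out, "vc_eff") <- vc_i
  out
}

eta_full <- function(eta) {
  out <- c(kg = 0, kel = 0, vc = 0)
  if (length(eta)) {
    stopifnot(!is.null(names(eta)), all(names(eta) %in% names(out)))
    out[names(eta)] <- eta
  }
  out
}

kappa_full <- function(kappa) {
  out <- c(kel = 0, vc = 0)
  if (length(kappa)) {
    stopifnot(!is.null(names(kappa)), all(names(kappa) %in% names(out)))
    out[names(kappa)] <- kappa
  }
  out
}

#' Closed-form fasted cascade concentration
#'
#' Under fasted conditions all rates are constant and the drug subsystem
#' is a linear three-stage catenary chain, whose central amount after a
#' bolus into the stomach is the classical three-exponential (Bateman)
#' solution. Multiple doses superpose. This closed form is exact and is
#' used throughout the test-suite as an independent oracle for the
#' numerical integrator.
#'
#' @param t Times (h).
#' @param dose Dose amount(s) (mg); recycled against `dose_times`.
#' @param dose_times Dosing times (h).
#' @param kg,kma,kel First-order rate constants (1/h), pairwise distinct.
#' @param vc Apparent volume (L).
#' @return Concentration vector (ug/mL) at `t`.
#' @examples
#' cascade_conc(c(1, 4, 12, 24, 72), 250, 0, 0.0412, 0.198, 0.27, 12.9)
#' @export
cascade_conc <- function(t, dose, dose_times, kg, kma, kel, vc) {
  stopifnot(kg > 0, kma > 0, kel > 0, vc > 0)
  if (min(abs(c(kg - kma, kg - kel, kma - kel))) < 1e-10)
    stop("cascade closed form requires pairwise distinct rate constants",
         call. = FALSE)
  dose <- rep_len(dose, length(dose_times))
  one <- function(tt) {
    kg * kma * (
      exp(-kg * tt) / ((kma - kg) * (kel - kg)) +
      exp(-kma * tt) / ((kg - kma) * (kel - kma)) +
      exp(-kel * tt) / ((kg - kel) * (kma - kel)))
  }
  out <- numeric(length(t))
  for (j in seq_along(dose_times)) {
    td <- t - dose_times[j]
    out <- out + ifelse(td < 0, 0, one(pmax(td, 0)) * dose[j])
  }
  out / vc
}

#' Closed-form calorie kinetics
#'
#' The calorie subsystem is an independent two-stage chain: calories empty
#' from the stomach at `kg_prime` and leave the duodenum at `k_out`.
#' For a single meal of `x4_0` calorie units at time 0,
#' `x5(t) = kg_prime * x4_0 * (exp(-kg_prime t) - exp(-k_out t)) /
#' (k_out - kg_prime)`, with the confluent limit
#' `kg_prime * x4_0 * t * exp(-kg_prime t)` when the two rates are within
#' `1e-8` of each other.
#'
#' @param t Times since the meal (h, >= 0).
#' @param x4_0 Meal size (calorie units).
#' @param kg_prime,k_out Rate constants (1/h).
#' @return A data.frame with columns `time`, `x4`, `x5`.
#' @examples
#' calorie_kinetics(c(1, 24, 96), 6.863, 0.00971, 0.00972)
#' @export
calorie_kinetics <- function(t, x4_0, kg_prime, k_out) {
  stopifnot(all(t >= 0), x4_0 >= 0, kg_prime > 0, k_out > 0)
  x4 <- x4_0 * exp(-kg_prime * t)
  if (abs(k_out - kg_prime) < 1e-8) {
    x5 <- kg_prime * x4_0 * t * exp(-kg_prime * t)
  } else {
    x5 <- kg_prime * x4_0 * (exp(-kg_prime * t) - exp(-k_out * t)) /
      (k_out - kg_prime)
  }
  data.frame(time = t, x4 = x4, x5 = x5)
}

#' Fed-state derived parameters
#'
#' Reports the fed-state typical parameter values and their percent change
#' from fasted, at the reporting convention of evaluating the bile effect
#' at the full meal-calorie load (the dynamic duodenal calorie amount in a
#' simulation never reaches that load because calories empty slowly; the
#' convention makes the bile effect commensurate with the printed meal
#' sizes). The bioavailability fold-change reads the drop in apparent
#' volume as a rise in F: `fold = 1 / (1 + e_vc)`.
#'
#' @param params An `mbpk_params` object.
#' @param meal_calories Meal size (kcal).
#' @param food_type `"standard"` or `"high_fat"` (or `"fasted"`, giving
#'   the identity report).
#' @return A data.frame with one row per quantity: `kg_fed`, `kma_fed`,
#'   `vc_fed`, `bioavailability_fold`, their fasted references and percent
#'   change.
#' @examples
#' derived_fed_parameters(mbpk_params(), 686.3, "standard")
#' derived_fed_parameters(mbpk_params(), 908, "high_fat")
#' @export
derived_fed_parameters <- function(params, meal_calories, food_type) {
  stopifnot(inherits(params, "mbpk_params"), meal_calories >= 0)
  food_type <- match.arg(food_type, FOOD_TYPES)
  fed <- food_type != "fasted"
  x5 <- if (fed) meal_calories / params$calorie_unit_kcal else 0
  kg_fed <- effective_kg(params$tv_kg, params$e_food, as.integer(fed))
  kma_fed <- effective_kma(params$k_ma, params$e_bile, x5)
  vc_fed <- effective_vc(params$vc_over_f, food_type, params$e_vc1,
                         params$e_vc2)
  e_vc <- switch(food_type, fasted = 0, standard = params$e_vc1,
                 high_fat = params$e_vc2)
  fold <- 1 / (1 + e_vc)
  data.frame(
    quantity = c("kg_fed", "kma_fed", "vc_fed", "bioavailability_fold"),
    value = c(kg_fed, kma_fed, vc_fed, fold),
    fasted = c(params$tv_kg, params$k_ma, params$vc_over_f, 1),
    percent_change = c(
      100 * (kg_fed / params$tv_kg - 1),
      100 * (kma_fed / params$k_ma - 1),
      100 * (vc_fed / params$vc_over_f - 1),
      100 * (fold - 1)
    ),
    units = c("1/h", "1/h", "L", "fold"),
    row.names = NULL
  )
}
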