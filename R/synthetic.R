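#' Three-way crossover trial design
#'
#' The design the model was developed on: healthy subjects, three periods
#' (fasted / standard meal / high-fat meal), a single 250 mg
#' sustained-release dose per period taken with the period meal, rich
#' sampling to 72 h, and a washout long enough that periods are
#' independent.
#'
#' @param n_subjects Number of subjects.
#' @param periods Data.frame with columns `food_type` and `calories`, one
#'   row per period. Default: fasted 0 kcal, standard 686.3 kcal,
#'   high-fat 1280 kcal (set `high_fat_calories = 908` for the
#'   derived-parameter reporting convention).
#' @param dose Dose (mg).
#' @param sampling_times Post-dose sampling times (h, sorted, > 0).
#' @param washout Washout between periods (h). Periods are simulated
#'   independently (single dose, no carryover); the washout only sets the
#'   cumulative time axis.
#' @param high_fat_calories Calories of the high-fat period when using the
#'   default periods.
#' @return A list of class `trial_design`.
#' @examples
#' trial_design(n_subjects = 6)
#' @export
trial_design <- function(n_subjects = 24,
                         periods = NULL,
                         dose = 250,
                         sampling_times = c(1, 2, 3, 4, 5, 6, 8, 10, 12,
                                            24, 48, 72),
                         washout = 168,
                         high_fat_calories = 1280) {
  if (is.null(periods)) {
    periods <- data.frame(
      food_type = c("fasted", "standard", "high_fat"),
      calories = c(0, 686.3, high_fat_calories)
    )
  }
  stopifnot(n_subjects >= 1, nrow(periods) >= 1,
            all(periods$food_type %in% FOOD_TYPES),
            all(periods$calories >= 0),
            all(sampling_times > 0), !is.unsorted(sampling_times),
            dose > 0, washout >= 0)
  if (any(periods$food_type == "fasted" & periods$calories > 0))
    stop("fasted periods must have 0 kcal", call. = FALSE)
  structure(list(n_subjects = n_subjects, periods = periods, dose = dose,
                 sampling_times = as.numeric(sampling_times),
                 washout = washout),
            class = "trial_design")
}

#' Generate a synthetic crossover trial
#'
#' Draws IIV deviates per subject and IOV deviates per subject-period,
#' simulates each period's residual-error-free profile with the
#' mechanistic model, applies proportional residual error (negative draws
#' rejected and redrawn), and emits the dataset in the delimited dialect
#' of [as_pk_dataset()] together with the hidden true random effects for
#' parameter-recovery experiments. Each period contributes a dose row
#' (carrying the meal calories and food code), a flagged pre-dose zero
#' sample and one observation row per sampling time; period `p` of a
#' subject starts at cumulative time `(p-1) * (max(sampling) + washout)`.
#'
#' @param design A [trial_design()].
#' @param params An `mbpk_params` object (generating truth).
#' @param seed Integer seed; the trial is fully reproducible from it.
#' @return A list with `dataset` (a `pk_dataset`), `truth` (per
#'   subject-period realized random effects from
#'   [sample_random_effects()]), `seed`, `design` and `n_redrawn` (count
#'   of rejected negative residual draws).
#' @examples
#' trial <- generate_trial(trial_design(n_subjects = 2), mbpk_params(),
#'                         seed = 42)
#' head(trial$dataset)
#' @export
generate_trial <- function(design, params, seed) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "mbpk_params"))
  set.seed(seed)
  n_per <- nrow(design$periods)
  truth <- sample_random_effects(params, design$n_subjects, n_per,
                                 food_types = design$periods$food_type)
  period_len <- max(design$sampling_times) + design$washout
  st <- design$sampling_times

  rows <- vector("list", nrow(truth))
  n_redrawn <- 0L
  for (r in seq_len(nrow(truth))) {
    subj <- truth$subject[r]
    per <- truth$occasion[r]
    ft <- design$periods$food_type[per]
    cal <- design$periods$calories[per]
    sch <- if (ft == "fasted") {
      event_schedule(0, design$dose, food_type = "fasted")
    } else {
      event_schedule(0, design$dose, meal_times = 0, meal_calories = cal,
                     food_type = ft)
    }
    prof <- solve_profile(
      params, sch, st,
      eta = c(kg = truth$eta_kg[r], kel = truth$eta_kel[r],
              vc = truth$eta_vc[r]),
      kappa = c(kel = truth$kappa_kel[r], vc = truth$kappa_vc[r])
    )
    dv <- apply_residual_error(prof$conc, params$sigma_prop)
    n_redrawn <- n_redrawn + attr(dv, "n_redrawn")
    t0 <- (per - 1) * period_len
    code <- food_type_code(ft)
    rows[[r]] <- data.frame(
      ID = subj,
      TIME = t0 + c(0, 0, st),
      AMT = c(design$dose, 0, numeric(length(st))),
      DV = c(0, 0, as.numeric(dv)),
      EVID = c(1, 0, integer(length(st))),
      MDV = c(1, 1, integer(length(st))),
      OCC = per,
      FOOD = code,
      CAL = c(cal, 0, numeric(length(st)))
    )
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$ID, df$TIME, -df$EVID), ]
  rownames(df) <- NULL
  list(dataset = as_pk_dataset(df), truth = truth, seed = seed,
       design = design, n_redrawn = n_redrawn)
}
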