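p0 <- default_params()

test_that("food window indicator follows the change-point definition", {
  # active inside the fitted 6.94 h window, fed only
  expect_identical(food_window_indicator(3, 0, 0, 6.94, fed = TRUE), 1L)
  expect_identical(food_window_indicator(8, 0, 0, 6.94, fed = TRUE), 0L)
  expect_identical(food_window_indicator(3, 0, 0, 6.94, fed = FALSE), 0L)
  # half-open: boundary belongs to the outside at the end only
  expect_identical(food_window_indicator(c(0, 6.94), 0, 0, 6.94, TRUE),
                   c(1L, 0L))
  # window anchored to the meal time
  expect_identical(food_window_indicator(25, 24, 0, 6.94, TRUE), 1L)
  expect_error(food_window_indicator(-1, 0, 0, 6.94, TRUE), "non-negative")
  expect_error(food_window_indicator(1, 0, 3, 3, TRUE))
})

test_that("effective rates reproduce the published fed-state arithmetic", {
  expect_equal(effective_kg(0.0412, 0.617, 1), 0.067, tolerance = 1e-2)
  expect_equal(effective_kg(0.0412, 0.617, 1), 0.0412 * 1.617)
  expect_equal(effective_kg(0.0412, 0.617, 0), 0.0412)
  expect_equal(effective_kg(0.1, 0, 1), 0.1)
  expect_error(effective_kg(0.1, -1, 1), "-1")

  expect_equal(round(effective_kma(0.198, 0.0239, 6.863), 2), 0.23)
  expect_equal(round(effective_kma(0.198, 0.0239, 9.08), 2), 0.24)
  expect_equal(effective_kma(0.198, 0.0239, 0), 0.198)
  expect_error(effective_kma(0.198, -0.5, 10), "positive")

  expect_equal(effective_vc(12.9, "standard"), 7.8174)
  expect_equal(round(effective_vc(12.9, "standard"), 2), 7.82)
  expect_equal(round(effective_vc(12.9, "high_fat"), 2), 6.95)
  expect_equal(effective_vc(12.9, "fasted"), 12.9)
  expect_error(effective_vc(12.9, "second_breakfast"))
})

test_that("ode right-hand side matches hand evaluation and the solution", {
  sch <- event_schedule(0, 250)
  expect_equal(ode_rhs(numeric(5), 1, p0, sch), numeric(5))
  d <- ode_rhs(c(250, 0, 0, 0, 0), 0.5, p0, sch)
  expect_equal(d[1], -0.0412 * 250) # = -10.3 mg/h
  expect_equal(d[2], +0.0412 * 250)
  expect_equal(d[3:5], numeric(3))

  # rhs equals a central finite difference of the integrated trajectory,
  # fed defaults, away from the window boundary
  fed <- event_schedule(0, 250, meal_times = 0, meal_calories = 686.3,
                        food_type = "standard")
  h <- 1e-3
  t0 <- 3
  tg <- c(t0 - h, t0, t0 + h)
  st <- attr(solve_profile(p0, fed, tg), "states")[, 1:5]
  fd <- (st[3, ] - st[1, ]) / (2 * h)
  expect_equal(unname(fd), ode_rhs(unname(st[2, ]), t0, p0, fed),
               tolerance = 1e-6)
})

test_that("numerical solution equals the closed-form fasted cascade", {
  tg <- c(1, 4, 12, 24, 72)
  prof <- solve_profile(p0, event_schedule(0, 250), tg)
  oracle <- cascade_conc(tg, 250, 0, p0$tv_kg, p0$k_ma, p0$k_el,
                         p0$vc_over_f)
  expect_equal(prof$conc, oracle, tolerance = 1e-6)
  # everywhere on a dense grid, multiple doses
  tg2 <- seq(0.5, 120, by = 0.5)
  prof2 <- solve_profile(p0, event_schedule(c(0, 24, 48), 250), tg2)
  oracle2 <- cascade_conc(tg2, 250, c(0, 24, 48), p0$tv_kg, p0$k_ma,
                          p0$k_el, p0$vc_over_f)
  expect_equal(prof2$conc, oracle2, tolerance = 1e-6)
})

test_that("calorie subsystem matches its closed form incl. equal rates", {
  tg <- c(0.5, 2, 6, 24, 96)
  sch <- event_schedule(0, 250, meal_times = 0, meal_calories = 686.3,
                        food_type = "standard")
  st <- attr(solve_profile(p0, sch, tg), "states")
  ck <- calorie_kinetics(tg, 6.863, p0$kg_prime, p0$k_out)
  expect_equal(unname(st[, "x4"]), ck$x4, tolerance = 1e-8)
  expect_equal(unname(st[, "x5"]), ck$x5, tolerance = 1e-8)

  # exactly equal rates: the confluent limit form
  ck_eq <- calorie_kinetics(tg, 5, 0.01, 0.01)
  expect_equal(ck_eq$x5, 0.01 * 5 * tg * exp(-0.01 * tg))
  # continuity: near-equal rates approach the limit form
  ck_near <- calorie_kinetics(tg, 5, 0.01, 0.01 + 5e-7)
  expect_equal(ck_near$x5, ck_eq$x5, tolerance = 1e-4)
})

test_that("dose of zero gives an all-zero profile", {
  sch <- event_schedule(0, 250)
  prof <- solve_profile(p0, sch, c(1, 10))
  expect_true(all(prof$conc > 0))
  # no dose events at all: empty schedule is rejected upstream, use a
  # meal-only run
  meal_only <- event_schedule(100, 1e-12, meal_times = 0,
                              meal_calories = 500, food_type = "standard")
  prof0 <- solve_profile(p0, meal_only, c(1, 10, 50))
  expect_equal(prof0$conc, rep(0, 3), tolerance = 1e-13)
})

test_that("mass balance holds for drug and calories along the trajectory", {
  sch <- event_schedule(c(0, 24), 250, meal_times = c(0, 24),
                        meal_calories = 908, food_type = "high_fat")
  tg <- seq(0, 96, by = 0.5)
  st <- attr(solve_profile(p0, sch, tg), "states")
  drug_total <- st[, "x1"] + st[, "x2"] + st[, "x3"] + st[, "drug_eliminated"]
  cal_total <- st[, "x4"] + st[, "x5"] + st[, "cal_eliminated"]
  dosed <- 250 * (1 + (tg >= 24))
  fed <- 9.08 * (1 + (tg >= 24))
  expect_equal(unname(drug_total), dosed, tolerance = 1e-8)
  expect_equal(unname(cal_total), fed, tolerance = 1e-8)
  expect_true(all(st >= -1e-12))
})

test_that("absorption-rate effects reshape but never add exposure", {
  # AUC to effectively-infinite time is invariant to e_bile and e_food;
  # Cmax is non-decreasing in e_bile
  tg <- seq(0, 2000, by = 1)
  mk <- function(e_bile, e_food) {
    pp <- update_mbpk_params(p0, e_bile = e_bile, e_food = e_food)
    sch <- event_schedule(0, 250, meal_times = 0, meal_calories = 908,
                          food_type = "high_fat")
    solve_profile(pp, sch, tg)$conc
  }
  base <- mk(0.0239, 0.617)
  no_bile <- mk(0, 0.617)
  no_food <- mk(0.0239, 0)
  auc <- function(cc) sum(diff(tg) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(auc(base), auc(no_bile), tolerance = 1e-5)
  expect_equal(auc(base), auc(no_food), tolerance = 1e-5)
  expect_gte(max(base), max(no_bile))

  # concentration scales exactly as 1/Vc
  p_half <- update_mbpk_params(p0, vc_over_f = p0$vc_over_f * 2)
  sch <- event_schedule(0, 250)
  c1 <- solve_profile(p0, sch, c(2, 10, 40))$conc
  c2 <- solve_profile(p_half, sch, c(2, 10, 40))$conc
  expect_equal(c1, 2 * c2, tolerance = 1e-12)
})

test_that("with no calories and no food effect, fed equals fasted", {
  pp <- update_mbpk_params(p0, e_food = 0)
  tg <- c(1, 5, 12, 48)
  fasted <- solve_profile(pp, event_schedule(0, 250), tg)$conc
  # fed run with a zero-calorie meal: same drug subsystem, but the fed
  # Vc coefficient applies, so compare amounts
  fed_sch <- event_schedule(0, 250, meal_times = 0, meal_calories = 0,
                            food_type = "standard")
  st_fed <- attr(solve_profile(pp, fed_sch, tg), "states")
  st_fast <- attr(solve_profile(pp, event_schedule(0, 250), tg), "states")
  expect_equal(st_fed[, "x3"], st_fast[, "x3"], tolerance = 1e-10)
  expect_true(all(fasted > 0))
})

test_that("derived fed-state report reproduces the published table", {
  std <- derived_fed_parameters(p0, 686.3, "standard")
  hf <- derived_fed_parameters(p0, 908, "high_fat")
  val <- function(d, q) d$value[d$quantity == q]
  expect_equal(round(val(std, "kg_fed"), 3), 0.067)
  expect_equal(round(val(std, "kma_fed"), 2), 0.23)
  expect_equal(round(val(hf, "kma_fed"), 2), 0.24)
  expect_equal(round(val(std, "vc_fed"), 2), 7.82)
  expect_equal(round(val(hf, "vc_fed"), 2), 6.95)
  expect_equal(round(val(std, "bioavailability_fold"), 2), 1.65)
  expect_equal(round(val(hf, "bioavailability_fold"), 2), 1.86)
  # percent changes as printed
  pc <- function(d, q) d$percent_change[d$quantity == q]
  expect_equal(pc(std, "kg_fed"), 61.7, tolerance = 1e-10)
  expect_equal(round(pc(std, "kma_fed"), 1), 16.4) # 0.0239*6.863 = 16.40%
  expect_equal(round(pc(hf, "kma_fed"), 1), 21.7)

  # all effects off: fed equals fasted, fold 1
  pnull <- update_mbpk_params(p0, e_food = 0, e_bile = 0, e_vc1 = 1e-12,
                              e_vc2 = 1e-12)
  d0 <- derived_fed_parameters(pnull, 686.3, "standard")
  expect_equal(d0$value[1:3], d0$fasted[1:3], tolerance = 1e-9)
  expect_equal(val(d0, "bioavailability_fold"), 1, tolerance = 1e-9)
})
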