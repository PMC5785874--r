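p0 <- default_params()

test_that("conditional estimates solve the linear-Gaussian case exactly", {
  # single observation, identity-plus-intercept model: the posterior mode
  # is the closed-form ridge estimate omega^2/(omega^2+sigma^2) * resid
  omega <- 0.5
  sigma <- 0.2
  y <- 1.3
  ce <- conditional_estimates(y, function(b) 1 + b, omega, sigma,
                              error_model = "additive")
  expect_equal(ce$b_hat, 0.3 * omega^2 / (omega^2 + sigma^2),
               tolerance = 1e-7)
  # and its OFV equals the closed-form marginal normal -2LL
  V <- sigma^2 + omega^2
  expect_equal(ce$ofv, log(2 * pi * V) + 0.3^2 / V, tolerance = 1e-7)

  # shrinkage to zero as the prior tightens
  ce0 <- conditional_estimates(y, function(b) 1 + b, 1e-6, sigma,
                               error_model = "additive")
  expect_equal(ce0$b_hat, 0, tolerance = 1e-9)
})

test_that("conditional mode is start-independent on a convex problem", {
  p <- fixed_effect_params(omega_kel = 0.3)
  trial <- generate_trial(trial_design(n_subjects = 1,
                                       periods = data.frame(
                                         food_type = "fasted", calories = 0)),
                          default_params(), seed = 21)
  s <- fenofood:::build_subjects(trial$dataset)[[1]]
  layout <- fenofood:::re_layout(s, p)
  pf <- fenofood:::subject_pred_fn(s, p, layout, 1e-8, 1e-10)
  y <- s$occasions[[1]]$dv
  a <- conditional_estimates(y, pf, layout$omega, p$sigma_prop, start = 0)
  b <- conditional_estimates(y, pf, layout$omega, p$sigma_prop, start = 0.1)
  expect_equal(a$b_hat, b$b_hat, tolerance = 1e-6)
})

test_that("EBEs shrink to zero as residual error dominates", {
  # under additive error an uninformative likelihood leaves only the
  # prior, whose mode is zero (under proportional error the log-variance
  # interaction term still depends on the predictions, so full shrinkage
  # is an additive-error property)
  trial <- small_trial(n = 3, seed = 77)
  p_noisy <- update_mbpk_params(p0, sigma_prop = 500)
  res <- foce_objective(trial$dataset, p_noisy, return_ebe = TRUE,
                        error_model = "additive")
  for (b in res$ebe) expect_lt(max(abs(b)), 1e-2)
})

test_that("zero-variability hierarchy collapses to the pooled likelihood", {
  trial <- small_trial(n = 3, seed = 13)
  pz <- mbpk_params(omega_kg = 0, omega_kel = 0, omega_vc = 0,
                    pi_kel = 0, pi_vc = 0)
  ofv <- foce_objective(trial$dataset, pz)
  # naive-pooled -2LL computed directly from typical predictions
  subs <- fenofood:::build_subjects(trial$dataset)
  pooled <- 0
  for (s in subs) {
    for (occ in s$occasions) {
      sch <- event_schedule(occ$dose_times, occ$dose_amounts,
                            meal_times = occ$meal_times,
                            meal_calories = occ$meal_calories,
                            food_type = occ$food_type)
      f <- solve_profile(pz, sch, occ$obs_times)$conc
      v <- (pz$sigma_prop * f)^2
      pooled <- pooled + sum(log(2 * pi * v) + (occ$dv - f)^2 / v)
    }
  }
  expect_equal(ofv, pooled, tolerance = 1e-10)
})

test_that("FOCE objective equals the closed-form linear mixed model -2LL", {
  # identity prediction model through the generic engine: subjects with
  # constant prediction mu + b and additive error; the Laplace/FOCE-I
  # approximation is exact here
  set.seed(5)
  mu <- 10
  omega <- 2
  sigma <- 1.5
  y_by_subject <- lapply(1:6, function(i)
    mu + rnorm(1, 0, omega) + rnorm(5, 0, sigma))
  ofv <- sum(vapply(y_by_subject, function(y) {
    conditional_estimates(y, function(b) rep(mu + b, length(y)),
                          omega, sigma, error_model = "additive")$ofv
  }, numeric(1)))
  oracle <- lmm_neg2ll(y_by_subject, mu, omega, sigma)
  expect_equal(ofv, oracle, tolerance = 1e-4)
})

test_that("objective ignores subjects without observations and row order", {
  trial <- small_trial(n = 3, seed = 99)
  ofv <- foce_objective(trial$dataset, p0)
  # append a dose-only subject
  extra <- trial$dataset[trial$dataset$ID == 1 & trial$dataset$EVID == 1, ]
  extra$ID <- 99
  d2 <- as_pk_dataset(rbind(trial$dataset, extra))
  expect_equal(foce_objective(d2, p0), ofv, tolerance = 1e-9)
  # subject order invariance
  d3 <- trial$dataset[order(-trial$dataset$ID, trial$dataset$TIME,
                            -trial$dataset$EVID), ]
  expect_equal(foce_objective(as_pk_dataset(d3), p0), ofv, tolerance = 1e-8)
})

test_that("all-zero predictions with non-zero observations are flagged", {
  expect_error(
    conditional_estimates(c(1, 2), function(b) c(0, 0), 0.3, 0.5),
    "all-zero predictions")
})

test_that("noiseless zero-variability data are recovered to under 1%", {
  truth <- fixed_effect_params()
  trial <- generate_trial(trial_design(n_subjects = 4), truth, seed = 55)
  start <- update_mbpk_params(truth, tv_kg = 0.055, k_el = 0.2,
                              vc_over_f = 16, sigma_prop = 0.1)
  fit <- fit_mbpk(trial$dataset, start,
                  free = c("tv_kg", "k_el", "vc_over_f"))
  expect_lt(max(abs(fit$estimates[c("tv_kg", "k_el", "vc_over_f")] /
                      c(truth$tv_kg, truth$k_el, truth$vc_over_f) - 1)),
            0.01)
  # optimality: OFV at the fit is no worse than at the generating values
  expect_lte(fit$ofv,
             foce_objective(trial$dataset,
                            update_mbpk_params(truth, sigma_prop = 0.1)))
})

test_that("standard errors and RSE follow the asymptotic definitions", {
  truth <- fixed_effect_params(sigma_prop = 0.15)
  trial <- generate_trial(trial_design(n_subjects = 5), truth, seed = 66)
  fit <- fit_mbpk(trial$dataset, truth, free = c("tv_kg", "k_el"),
                  se = TRUE, control = list(restarts = 0))
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
  expect_equal(unname(fit$rse_percent),
               unname(100 * fit$se / abs(fit$estimates)))
  # with real residual noise in the data the SEs should be a few percent
  expect_lt(max(fit$rse_percent), 50)
})

test_that("fit refuses structurally fixed parameters and reports them", {
  trial <- small_trial(n = 2, seed = 1)
  expect_error(fit_mbpk(trial$dataset, p0, free = c("v_duodenum")),
               "fixed")
  expect_error(fit_mbpk(trial$dataset, p0, free = c("mtime1")), "fixed")
})
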