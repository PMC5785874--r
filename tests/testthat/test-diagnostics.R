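p0 <- default_params()

test_that("residuals vanish on a deterministic self-fit", {
  # data generated without noise or variability, fitted under additive
  # error (a proportional-error ML fit carries an O(sigma^2) downward
  # prediction bias from the log-variance term, so "CWRES ~ 0" is the
  # additive-error form of the self-consistency check)
  pz <- fixed_effect_params()
  trial <- generate_trial(trial_design(n_subjects = 2), pz, seed = 3)
  start <- update_mbpk_params(pz, sigma_prop = 0.1)
  fit <- fit_mbpk(trial$dataset, start, free = c("tv_kg"),
                  error_model = "additive")
  rt <- residual_table(trial$dataset, fit)
  expect_lt(max(abs(rt$CWRES)), 1e-3)
  expect_equal(rt$IPRED, rt$DV, tolerance = 1e-5)
  expect_equal(rt$PRED, rt$DV, tolerance = 1e-5)
})

test_that("CWRES equals the analytic standardized residual in the linear case", {
  # identity model f = mu + b with additive-like small proportional error:
  # check the decorrelation algebra directly on the package's formula
  # using one subject of the mechanistic model with a single random effect
  p <- mbpk_params(omega_kg = 0, omega_kel = 0, omega_vc = 0.4,
                   pi_kel = 0, pi_vc = 0)
  trial <- generate_trial(trial_design(n_subjects = 1,
                                       periods = data.frame(
                                         food_type = "fasted",
                                         calories = 0)), p, seed = 9)
  fit <- fit_mbpk(trial$dataset, p, free = c("tv_kg"),
                  control = list(iter.max = 5, restarts = 0))
  rt <- residual_table(trial$dataset, fit)

  # oracle: rebuild E and V from the same linearisation with independent
  # arithmetic (explicit eigen decomposition instead of Cholesky)
  s <- fenofood:::build_subjects(trial$dataset)[[1]]
  layout <- fenofood:::re_layout(s, fit$params)
  pf <- fenofood:::subject_pred_fn(s, fit$params, layout, 1e-8, 1e-10)
  b_hat <- unname(fit$ebe[[as.character(s$id)]])
  f_hat <- pf(b_hat)
  h <- 1e-4
  g <- (pf(b_hat + h) - f_hat) / h
  E <- f_hat - g * b_hat
  V <- outer(g, g) * layout$omega^2 +
    diag((fit$params$sigma_prop * f_hat)^2)
  ee <- eigen(V, symmetric = TRUE)
  y <- s$occasions[[1]]$dv
  # both decorrelations must give residual vectors with identical
  # Mahalanobis norm
  expect_equal(sum(rt$CWRES^2),
               drop(crossprod(y - E, solve(V, y - E))), tolerance = 1e-6)
  expect_true(all(is.finite(ee$values)) && all(ee$values > 0))
})

test_that("CWRES from a correctly specified model are standard-normal-ish", {
  trial <- generate_trial(trial_design(n_subjects = 15), p0, seed = 25)
  # self-evaluation at the generating parameters (no refit needed to
  # check the distributional property of the residual construction)
  fit <- fit_mbpk(trial$dataset, p0, free = c("tv_kg"),
                  control = list(iter.max = 3, restarts = 0))
  rt <- residual_table(trial$dataset, fit)
  expect_gt(nrow(rt), 500)
  expect_lt(abs(mean(rt$CWRES)), 0.1)
  expect_gt(var(rt$CWRES), 0.8)
  expect_lt(var(rt$CWRES), 1.2)
  # invariance to observation order: residuals keyed to rows, not order
  shuffled <- trial$dataset[sample(nrow(trial$dataset)), ]
  shuffled <- shuffled[order(shuffled$ID, shuffled$TIME, -shuffled$EVID), ]
  rt2 <- residual_table(as_pk_dataset(shuffled), fit)
  expect_equal(rt2[order(rt2$ID, rt2$TIME), "CWRES"],
               rt[order(rt$ID, rt$TIME), "CWRES"], tolerance = 1e-8)
})

test_that("vpc percentiles are monotone and bands behave with sigma", {
  trial <- generate_trial(trial_design(n_subjects = 6), p0, seed = 12)
  v <- vpc(trial$dataset, p0, n_replicates = 40, seed = 2)
  b <- v$bands
  expect_true(all(b$p5_obs <= b$p50_obs & b$p50_obs <= b$p95_obs))
  expect_true(all(b$p5_lo <= b$p5_hi & b$p50_lo <= b$p50_hi &
                    b$p95_lo <= b$p95_hi))
  # all three food strata at the nominal sampling times
  expect_setequal(unique(b$food_type), c("fasted", "standard", "high_fat"))
  expect_equal(sort(unique(b$time)),
               c(1, 2, 3, 4, 5, 6, 8, 10, 12, 24, 48, 72))

  # inflating residual error cannot narrow the simulated bands
  p_wide <- update_mbpk_params(p0, sigma_prop = 1.2)
  v2 <- vpc(trial$dataset, p_wide, n_replicates = 40, seed = 2)
  width <- function(x, pn) x$bands[[paste0(pn, "_hi")]] -
    x$bands[[paste0(pn, "_lo")]]
  expect_gt(mean(width(v2, "p95") - width(v, "p95")), 0)

  # two replicates with identical seeds: degenerate zero-width bands
  v3 <- vpc(trial$dataset, p0, n_replicates = 2, seed = c(7, 7))
  expect_equal(v3$bands$p50_lo, v3$bands$p50_hi, tolerance = 1e-12)
})

test_that("vpc rejects designs with empty bins", {
  trial <- generate_trial(trial_design(n_subjects = 3), p0, seed = 4)
  expect_error(vpc(trial$dataset, p0, n_replicates = 2, seed = 1,
                   bins = c(0, 30, 35, 80)), "empty bins")
})

test_that("subsample bootstrap is degenerate at fraction 1 and seeded", {
  pz <- fixed_effect_params()
  trial <- generate_trial(trial_design(n_subjects = 6), pz, seed = 6)
  bt <- mbpk_bootstrap(trial$dataset, pz, free = c("tv_kg"),
                       n_replicates = 3, fraction = 1, seed = 10,
                       control = list(iter.max = 10, restarts = 0))
  expect_equal(unname(bt$ci_lower), unname(bt$ci_upper), tolerance = 1e-10)
  expect_equal(bt$n_success, 3)

  b1 <- mbpk_bootstrap(trial$dataset, pz, free = c("tv_kg"),
                       n_replicates = 2, fraction = 0.9, seed = 1,
                       control = list(iter.max = 2, restarts = 0))
  b2 <- mbpk_bootstrap(trial$dataset, pz, free = c("tv_kg"),
                       n_replicates = 2, fraction = 0.9, seed = 2,
                       control = list(iter.max = 2, restarts = 0))
  expect_false(identical(b1$subject_sets, b2$subject_sets))
  expect_error(mbpk_bootstrap(trial$dataset[trial$dataset$ID <= 4, ], pz,
                              n_replicates = 2), "at least 5")
})
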