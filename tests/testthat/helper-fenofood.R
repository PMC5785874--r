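# Shared fixtures for the test-suite: everything is generated in code.

default_params <- function(...) mbpk_params(...)

# parameters with all variability switched off (deterministic model)
fixed_effect_params <- function(...) {
  base <- list(omega_kg = 0, omega_kel = 0, omega_vc = 0,
               pi_kel = 0, pi_vc = 0, sigma_prop = 1e-12)
  do.call(mbpk_params, utils::modifyList(base, list(...)))
}

small_trial <- function(n = 4, seed = 123, params = default_params()) {
  generate_trial(trial_design(n_subjects = n), params, seed = seed)
}

# Closed-form -2 log marginal likelihood of the one-random-intercept
# linear-Gaussian model y_ij = mu + b_i + eps: the oracle for the FOCE
# objective in the identity-model special case.
lmm_neg2ll <- function(y_by_subject, mu, omega, sigma) {
  total <- 0
  for (y in y_by_subject) {
    n <- length(y)
    V <- diag(sigma^2, n) + matrix(omega^2, n, n)
    r <- y - mu
    total <- total + n * log(2 * pi) +
      as.numeric(determinant(V, logarithm = TRUE)$modulus) +
      drop(crossprod(r, solve(V, r)))
  }
  total
}
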