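#' Population, individual predictions and conditional weighted residuals
#'
#' For every observation: `PRED`, the population prediction at zero
#' random effects; `IPRED`, the individual prediction at the empirical
#' Bayes estimates (EBEs); and `CWRES`, the residual decorrelated under
#' the FOCE linearisation: with `J` the sensitivity of the predictions to
#' the random effects at the EBE `b_hat`, the linearised marginal mean is
#' `E = f(b_hat) - J b_hat` and covariance
#' `V = J Omega J' + diag(var_res(f(b_hat)))` (interaction), and
#' `CWRES = L^{-1} (y - E)` with `L` the lower Cholesky factor of `V`.
#' For a correctly specified model CWRES are approximately standard
#' normal.
#'
#' @param dataset The `pk_dataset` the fit was obtained on.
#' @param fit An `mbpk_fit` from [fit_mbpk()].
#' @return A data.frame with one row per used observation: `ID`, `OCC`,
#'   `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(n_subjects = 3), mbpk_params(),
#'                         seed = 5)
#' fit <- fit_mbpk(trial$dataset, mbpk_params(), free = c("tv_kg"))
#' head(residual_table(trial$dataset, fit))
#' }
#' @export
residual_table <- function(dataset, fit) {
  stopifnot(inherits(fit, "mbpk_fit"))
  dataset <- as_pk_dataset(dataset)
  params <- fit$params
  subjects <- build_subjects(dataset)
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    if (s$n_obs == 0) next
    layout <- re_layout(s, params)
    pf <- subject_pred_fn(s, params, layout, fit$control$rtol,
                          fit$control$atol)
    y <- unlist(lapply(s$occasions[layout$occ_with_obs], `[[`, "dv"))
    b_hat <- fit$ebe[[as.character(s$id)]]
    if (is.null(b_hat)) b_hat <- numeric(layout$q)
    b_hat <- unname(b_hat)

    f_hat <- pf(b_hat)
    pred <- pf(numeric(layout$q))
    v <- if (fit$error_model == "proportional")
      pmax((params$sigma_prop * f_hat)^2, 1e-290) else
      rep(params$sigma_prop^2, length(f_hat))

    if (layout$q > 0) {
      J <- matrix(0, length(y), layout$q)
      h <- 1e-4
      for (k in seq_len(layout$q)) {
        bk <- b_hat
        bk[k] <- bk[k] + h
        J[, k] <- (pf(bk) - f_hat) / h
      }
      E <- f_hat - drop(J %*% b_hat)
      V <- J %*% diag(layout$omega^2, layout$q) %*% t(J) + diag(v)
    } else {
      E <- f_hat
      V <- diag(v, length(y))
    }
    L <- tryCatch(t(chol(V)), error = function(e)
      stop("singular linearised covariance for subject ", s$id,
           call. = FALSE))
    cwres <- drop(forwardsolve(L, y - E))

    times <- unlist(lapply(s$occasions[layout$occ_with_obs], `[[`,
                           "obs_times"))
    occ <- rep(vapply(s$occasions[layout$occ_with_obs], `[[`, numeric(1),
                      "occasion"),
               vapply(s$occasions[layout$occ_with_obs],
                      function(o) length(o$obs_times), integer(1)))
    out[[si]] <- data.frame(ID = s$id, OCC = occ, TIME = times, DV = y,
                            PRED = pred, IPRED = f_hat, CWRES = cwres)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets at the design of the input (same
#' subjects, occasions, doses, meals and sampling times), with fresh
#' random effects and proportional residual error, and summarises each
#' replicate's concentration percentiles per time bin, stratified by food
#' type. The band for each percentile is the 2.5th-97.5th percentile
#' across replicates; observed percentiles are computed from the input
#' dataset. Bins default to the nominal (occasion-local) sampling times
#' of the fixed design; numeric `bins` are treated as break points.
#'
#' @param dataset A `pk_dataset` providing both the design and the
#'   observations.
#' @param params An `mbpk_params` object to simulate from.
#' @param n_replicates Number of simulated datasets (>= 100 recommended;
#'   smaller values are allowed for degenerate checks).
#' @param percentiles Percentiles to track (in percent).
#' @param seed Scalar seed, or a vector of length `n_replicates` with one
#'   seed per replicate.
#' @param bins `"nominal"` or numeric break points.
#' @return An object of class `vpc_result`: data.frame `bands` with
#'   columns `food_type`, `time`, `n_obs`, and for each percentile the
#'   observed value and the simulated band `lo`/`hi`.
#' @examples
#' trial <- generate_trial(trial_design(n_subjects = 4), mbpk_params(),
#'                         seed = 3)
#' v <- vpc(trial$dataset, mbpk_params(), n_replicates = 30, seed = 9)
#' head(v$bands)
#' @export
vpc <- function(dataset, params, n_replicates = 1000,
                percentiles = c(5, 50, 95), seed = 1, bins = "nominal") {
  stopifnot(inherits(params, "mbpk_params"), n_replicates >= 2)
  dataset <- as_pk_dataset(dataset)
  subjects <- build_subjects(dataset)

  # flatten the observation design
  design <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(s$occasions, function(o) {
      if (length(o$obs_times) == 0) return(NULL)
      data.frame(id = s$id, occasion = o$occasion, food_type = o$food_type,
                 time = o$obs_times, dv = o$dv)
    }))
  }))
  if (is.character(bins)) {
    design$bin <- design$time
  } else {
    bins <- sort(as.numeric(bins))
    idx <- findInterval(design$time, bins, rightmost.closed = TRUE)
    centers <- (utils::head(bins, -1) + utils::tail(bins, -1)) / 2
    if (any(idx < 1 | idx >= length(bins)))
      stop("observations outside the bin breaks", call. = FALSE)
    design$bin <- centers[idx]
    counts <- table(factor(idx, levels = seq_along(centers)))
    if (any(counts == 0))
      stop("empty bins: ",
           paste(signif(centers[counts == 0], 4), collapse = ", "),
           call. = FALSE)
  }
  key <- interaction(design$food_type, design$bin, drop = TRUE)

  per_rep_seed <- length(seed) == n_replicates && n_replicates > 1
  if (!per_rep_seed) set.seed(seed[1])

  pnames <- paste0("p", percentiles)
  sim_q <- array(NA_real_, dim = c(n_replicates, nlevels(key),
                                   length(percentiles)),
                 dimnames = list(NULL, levels(key), pnames))
  for (r in seq_len(n_replicates)) {
    if (per_rep_seed) set.seed(seed[r])
    sim_dv <- numeric(nrow(design))
    pos <- 1L
    for (s in subjects) {
      eta <- c(kg = stats::rnorm(1, 0, params$omega_kg),
               kel = stats::rnorm(1, 0, params$omega_kel),
               vc = stats::rnorm(1, 0, params$omega_vc))
      for (o in s$occasions) {
        if (length(o$obs_times) == 0) next
        kappa <- c(kel = stats::rnorm(1, 0, params$pi_kel),
                   vc = stats::rnorm(1, 0, params$pi_vc))
        sch <- event_schedule(o$dose_times, o$dose_amounts,
                              meal_times = o$meal_times,
                              meal_calories = o$meal_calories,
                              food_type = o$food_type)
        prof <- solve_profile(params, sch, o$obs_times, eta = eta,
                              kappa = kappa)
        nobs <- length(o$obs_times)
        sim_dv[pos:(pos + nobs - 1L)] <-
          apply_residual_error(prof$conc, params$sigma_prop)
        pos <- pos + nobs
      }
    }
    for (lv in levels(key)) {
      sim_q[r, lv, ] <- stats::quantile(sim_dv[key == lv],
                                        percentiles / 100, names = FALSE)
    }
  }

  bands <- do.call(rbind, lapply(levels(key), function(lv) {
    sel <- key == lv
    row <- data.frame(food_type = design$food_type[sel][1],
                      time = design$bin[sel][1], n_obs = sum(sel))
    for (j in seq_along(percentiles)) {
      obs <- stats::quantile(design$dv[sel], percentiles[j] / 100,
                             names = FALSE)
      ci <- stats::quantile(sim_q[, lv, j], c(0.025, 0.975), names = FALSE)
      row[[paste0(pnames[j], "_obs")]] <- obs
      row[[paste0(pnames[j], "_lo")]] <- ci[1]
      row[[paste0(pnames[j], "_hi")]] <- ci[2]
    }
    row
  }))
  bands <- bands[order(bands$food_type, bands$time), ]
  rownames(bands) <- NULL
  structure(list(bands = bands, n_replicates = n_replicates,
                 percentiles = percentiles, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d replicates, percentiles %s, %d bins\n",
              x$n_replicates, paste(x$percentiles, collapse = "/"),
              nrow(x$bands)))
  cat(sprintf("Coverage of observed percentiles by the 95%% bands: %.1f%%\n",
              100 * vpc_coverage(x)))
  invisible(x)
}

#' @param x A `vpc_result`.
#' @param food_type Stratum to draw; defaults to the first present.
#' @param log_y Draw the concentration axis on the log scale (zero
#'   observations are dropped from log-scale plots with a warning).
#' @param ... Further arguments passed to [graphics::plot()].
#' @describeIn vpc Draw one stratum: shaded simulated bands for each
#'   percentile with the observed percentiles overlaid.
#' @export
plot.vpc_result <- function(x, food_type = NULL, log_y = FALSE, ...) {
  b <- x$bands
  if (is.null(food_type)) food_type <- b$food_type[1]
  b <- b[b$food_type == food_type, ]
  if (nrow(b) == 0) stop("no bins for food type ", food_type, call. = FALSE)
  pnames <- paste0("p", x$percentiles)
  cols <- grDevices::adjustcolor("steelblue", alpha.f = 0.3)
  vals <- unlist(b[c(paste0(pnames, "_hi"), paste0(pnames, "_lo"),
                     paste0(pnames, "_obs"))])
  ymax <- max(vals)
  ylim <- c(if (log_y) min(vals[vals > 0]) else 0, ymax)
  if (log_y) {
    n_zero <- sum(unlist(b[paste0(pnames, "_obs")]) == 0)
    if (n_zero > 0)
      warning(n_zero, " zero values dropped from the log-scale plot")
  }
  graphics::plot(NA, xlim = range(b$time), ylim = ylim,
                 log = if (log_y) "y" else "",
                 xlab = "time (h)", ylab = "concentration (ug/mL)",
                 main = paste("VPC -", food_type), ...)
  for (pn in pnames) {
    graphics::polygon(c(b$time, rev(b$time)),
                      c(b[[paste0(pn, "_lo")]], rev(b[[paste0(pn, "_hi")]])),
                      col = cols, border = NA)
    graphics::lines(b$time, b[[paste0(pn, "_obs")]], type = "b", pch = 16)
  }
  invisible(x)
}

#' Fraction of VPC bins whose observed percentile lies inside the band
#'
#' @param v A `vpc_result`.
#' @return Fraction in `[0, 1]` across all bins and tracked percentiles.
#' @export
vpc_coverage <- function(v) {
  stopifnot(inherits(v, "vpc_result"))
  pnames <- paste0("p", v$percentiles)
  hits <- 0L
  tot <- 0L
  for (pn in pnames) {
    obs <- v$bands[[paste0(pn, "_obs")]]
    lo <- v$bands[[paste0(pn, "_lo")]]
    hi <- v$bands[[paste0(pn, "_hi")]]
    hits <- hits + sum(obs >= lo & obs <= hi)
    tot <- tot + length(obs)
  }
  hits / tot
}

#' Subsample bootstrap of the model fit
#'
#' Replicates draw `floor(fraction * N)` subjects *without replacement*
#' (default 90\%, the subsampling flavour used to validate the original
#' analysis), refit the model, and record the estimates; the classical
#' resample-with-replacement bootstrap is available via
#' `replace = TRUE`. Non-converged replicates are recorded and skipped;
#' more than 50\% failures is an error.
#'
#' @param dataset A `pk_dataset`.
#' @param start Starting/fixed parameter values, see [fit_mbpk()].
#' @param free Parameters to estimate, see [fit_mbpk()].
#' @param n_replicates Number of replicates.
#' @param fraction Subsample fraction in (0, 1].
#' @param replace Draw subjects with replacement (classical bootstrap).
#' @param seed Integer seed.
#' @param error_model,control Passed to [fit_mbpk()].
#' @return An object of class `boot_result`: `replicates` (one row per
#'   successful replicate), `median`, `ci_lower`, `ci_upper` (95\%
#'   percentile interval), `n_success`, `subject_sets`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(n_subjects = 6), mbpk_params(),
#'                         seed = 2)
#' bt <- mbpk_bootstrap(trial$dataset, mbpk_params(), free = c("tv_kg"),
#'                      n_replicates = 5, seed = 4)
#' bt$median
#' }
#' @export
mbpk_bootstrap <- function(dataset, start = mbpk_params(),
                           free = c("tv_kg", "k_ma", "k_el", "vc_over_f"),
                           n_replicates = 1000, fraction = 0.9,
                           replace = FALSE, seed = 1,
                           error_model = "proportional", control = list()) {
  stopifnot(fraction > 0, fraction <= 1)
  dataset <- as_pk_dataset(dataset)
  ids <- unique(dataset$ID)
  if (length(ids) < 5) stop("bootstrap needs at least 5 subjects",
                            call. = FALSE)
  m <- floor(fraction * length(ids))
  set.seed(seed)

  reps <- matrix(NA_real_, n_replicates, length(free),
                 dimnames = list(NULL, free))
  sets <- vector("list", n_replicates)
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    take <- sample(ids, m, replace = replace)
    sets[[r]] <- take
    pieces <- lapply(seq_along(take), function(i) {
      d <- dataset[dataset$ID == take[i], ]
      d$ID <- i  # relabel so duplicated subjects stay distinct
      d
    })
    boot_data <- as_pk_dataset(do.call(rbind, pieces))
    fit <- tryCatch(
      fit_mbpk(boot_data, start, free = free, error_model = error_model,
               se = FALSE, control = control),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence > 1) {
      failures <- failures + 1L
    } else {
      reps[r, ] <- fit$estimates
    }
  }
  if (failures > n_replicates / 2)
    stop("more than 50% of bootstrap replicates failed (", failures, "/",
         n_replicates, ")", call. = FALSE)
  ok <- stats::complete.cases(reps)
  structure(list(
    replicates = as.data.frame(reps[ok, , drop = FALSE]),
    median = apply(reps[ok, , drop = FALSE], 2, stats::median),
    ci_lower = apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                     probs = 0.025),
    ci_upper = apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                     probs = 0.975),
    n_success = sum(ok), n_replicates = n_replicates,
    fraction = fraction, replace = replace, seed = seed,
    subject_sets = sets
  ), class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d successful replicates (fraction %.2f%s)\n",
              x$n_success, x$n_replicates, x$fraction,
              if (x$replace) ", with replacement" else ", subsample"))
  print(data.frame(median = signif(x$median, 4),
                   ci95_lower = signif(x$ci_lower, 4),
                   ci95_upper = signif(x$ci_upper, 4)))
  invisible(x)
}
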