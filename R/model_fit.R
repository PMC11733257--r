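#' Simulation configuration for spectral fitting
#'
#' Bundles the fixed model structure used on every objective evaluation.
#' The free parameters (noise gain, noise filter constant, conflict
#' threshold) are supplied separately by the optimiser.
#'
#' @param body,ctrl Fixed plant and controller parameters.
#' @param mode,leak_tau Conflict-estimator structure (the threshold itself
#'   is free).
#' @param gains Gain conditions entering the objective (default: the
#'   9-gain study grid).
#' @param duration Simulated run length per condition (s). 410 s (ten
#'   40-s segments after the 10-s discard) is the routine protocol;
#'   2810 s (seventy segments) reproduces the full-resolution protocol.
#' @param device_lag Robot latency (s) in the simulations.
#' @param discard_s Leading time (s) discarded before spectra.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(body = body_params(), ctrl = control_params(body),
                       mode = "deadzone", leak_tau = Inf,
                       gains = study_gains(), duration = 410,
                       device_lag = 0, discard_s = 10) {
  structure(list(body = body, ctrl = ctrl, mode = mode, leak_tau = leak_tau,
                 gains = gains, duration = duration,
                 device_lag = device_lag, discard_s = discard_s),
            class = "fit_config")
}

#' Simulate per-gain velocity spectra at given free parameters
#'
#' Runs the closed-loop model once per gain (shared noise seed, so
#' evaluations are repeatable) and computes the velocity spectrum of the
#' simulated trunk position through the empirical pipeline (zero-phase
#' low-pass, central difference, 40-s segment-averaged PSD).
#'
#' @param params Numeric `c(k_noise, tau_noise, Te)`.
#' @param config A [fit_config()].
#' @param seed Integer seed reused for every evaluation.
#' @return Named list (one per gain) of `spectrum_psd`; divergent runs
#'   yield `NULL` entries.
#' @export
simulated_velocity_spectra <- function(params, config = fit_config(),
                                       seed = 1L) {
  np <- noise_params(k_noise = params[1], tau_noise = params[2], seed = seed)
  cp <- conflict_params(Te = params[3], mode = config$mode,
                        leak_tau = config$leak_tau)
  out <- lapply(config$gains, function(g) {
    tr <- simulate_trial(config$body, config$ctrl, cp, np,
                         gain_condition(G = g, device_lag = config$device_lag),
                         duration = config$duration)
    min_n <- (config$discard_s + 40) * tr$fs
    if (tr$diverged || length(tr$x_body) < min_n) return(NULL)
    v <- lowpass_then_differentiate(tr$x_body, fs = tr$fs)
    segmented_psd(v, fs = tr$fs, segment_s = 40, discard_s = config$discard_s)
  })
  names(out) <- format_gain(config$gains)
  out
}

#' 1/f-weighted spectral objective
#'
#' Residuals between target and simulated velocity spectra, stacked over
#' the 0.025-4 Hz band and all gain conditions, each bin weighted by
#' `sqrt(1/f)` so the summed squared objective weights squared errors by
#' `1/f`. Divergent simulations contribute constant penalty residuals of
#' `1000 * max(target)` so the optimiser retreats smoothly from
#' infeasible regions.
#'
#' @param params Numeric `c(k_noise, tau_noise, Te)`.
#' @param target Named list (by gain label) of target velocity
#'   `spectrum_psd` sharing the 0.025-Hz grid.
#' @param config A [fit_config()]; its gains must match `target`.
#' @param seed Seed reused on every evaluation (repeatable noise).
#' @param band Frequency band (Hz) summed over.
#' @return List with `residuals` (vector over gain x frequency) and
#'   `value` (sum of squares).
#' @export
spectral_objective <- function(params, target, config = fit_config(),
                               seed = 1L, band = c(0.025, 4)) {
  labs <- format_gain(config$gains)
  if (!all(labs %in% names(target)))
    stop("target spectra missing for gain(s): ",
         paste(setdiff(labs, names(target)), collapse = ", "), call. = FALSE)
  if (any(vapply(target[labs], is.null, logical(1))))
    stop("target spectrum missing (NULL) for some gain: targets must come ",
         "from non-divergent runs", call. = FALSE)
  sims <- simulated_velocity_spectra(params, config, seed)
  penalty <- 1000 * max(vapply(target[labs], function(sp) max(sp$S),
                               numeric(1)))
  res <- unlist(lapply(labs, function(lab) {
    tg <- target[[lab]]
    idx <- tg$f >= band[1] - 1e-9 & tg$f <= band[2] + 1e-9
    f <- tg$f[idx]
    sim <- sims[[lab]]
    if (is.null(sim)) return(rep(penalty, sum(idx)))
    if (length(sim$f) != length(tg$f) || max(abs(sim$f - tg$f)) > 1e-9)
      stop("target and simulated spectra are on different grids",
           call. = FALSE)
    sqrt(1 / f) * (tg$S[idx] - sim$S[idx])
  }))
  list(residuals = res, value = sum(res^2))
}

#' Fit the model's noise and threshold parameters to target spectra
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm]) on the
#' log of `(k_noise, tau_noise, Te)` — enforcing positivity — against the
#' 1/f-weighted residual vector of [spectral_objective()], from one or
#' several starting points. The same noise seed is reused on every
#' evaluation so the objective is deterministic; all starts and the basin
#' each converged to are recorded as a multi-start diagnostic.
#'
#' @param target Named list of target velocity spectra (by gain label).
#' @param starts Matrix or list of start vectors `c(k_noise, tau_noise,
#'   Te)`; a single vector is promoted.
#' @param config A [fit_config()].
#' @param seed Seed for the repeatable noise realisation.
#' @param lower,upper Box bounds on the parameters (natural scale).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A `fit_result`: fitted `k_noise_hat`, `tau_noise_hat`,
#'   `Te_hat`, `objective`, `n_evals`, `starts` (per-start table),
#'   `noise_seed`, `converged`.
#' @export
fit_parameters <- function(target, starts, config = fit_config(), seed = 1L,
                           lower = c(1e-4, 0.05, 1e-4),
                           upper = c(0.1, 20, 1),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ftol = 1e-10, ptol = 1e-8)) {
  if (!is.list(starts)) {
    if (is.matrix(starts)) starts <- split(starts, row(starts))
    else starts <- list(starts)
  }
  if (length(starts) < 1) stop("need at least one start", call. = FALSE)
  n_evals <- 0L
  fn <- function(logp) {
    n_evals <<- n_evals + 1L
    spectral_objective(exp(logp), target, config, seed)$residuals
  }
  runs <- lapply(starts, function(p0) {
    stopifnot(length(p0) == 3, all(p0 > 0))
    fit <- minpack.lm::nls.lm(par = log(p0), fn = fn,
                              lower = log(lower), upper = log(upper),
                              control = control)
    list(start = as.numeric(p0), par = exp(fit$par),
         objective = fit$deviance, info = fit$info,
         message = fit$message)
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  ok <- vapply(runs, function(r) r$info %in% 1:4, logical(1))
  if (!any(ok))
    stop("no start converged; per-start diagnostics:\n",
         paste(vapply(runs, function(r)
           sprintf("  start (%s): info %d, %s",
                   paste(signif(r$start, 3), collapse = ", "),
                   r$info, r$message), character(1)), collapse = "\n"),
         call. = FALSE)
  best <- runs[[which.min(replace(objs, !ok, Inf))]]
  start_tab <- data.frame(
    t(vapply(runs, function(r) c(r$start, r$par, r$objective), numeric(7))))
  names(start_tab) <- c("k_start", "tau_start", "Te_start",
                        "k_hat", "tau_hat", "Te_hat", "objective")
  structure(list(k_noise_hat = best$par[1], tau_noise_hat = best$par[2],
                 Te_hat = best$par[3], objective = best$objective,
                 n_evals = n_evals, starts = start_tab,
                 noise_seed = as.integer(seed),
                 converged = ok[which.min(replace(objs, !ok, Inf))]),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: k_noise = %.4g rad, tau_noise = %.4g s, Te = %.4g rad/s\n",
              x$k_noise_hat, x$tau_noise_hat, x$Te_hat))
  cat(sprintf("  objective = %.4g after %d evaluations (%d start(s), seed %d)\n",
              x$objective, x$n_evals, nrow(x$starts), x$noise_seed))
  invisible(x)
}
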