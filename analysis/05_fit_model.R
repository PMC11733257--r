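#!/usr/bin/env Rscript
# Stage 5 — fit the model's free parameters to the experiment's spectra.
#
# The three free parameters (noise gain, noise filter constant, conflict
# threshold Te) are fitted by Levenberg-Marquardt least squares on the
# 1/f-weighted difference between the condition-mean velocity spectra of
# the (synthetic) experiment and spectra simulated at candidate
# parameters, summed over 0.025-4 Hz and all nine gain conditions, with a
# repeatable noise realisation per evaluation. Two starts probe the
# basin. Requires stage 3's condition_spectra.csv.

suppressPackageStartupMessages(library(hapticsway))
spec <- read.csv("results/condition_spectra.csv",
                 colClasses = c(condition = "character"))
gl <- format_gain(study_gains())
target <- lapply(gl, function(cond) {
  d <- spec[spec$condition == cond & spec$measure == "velocity", ]
  structure(list(f = d$f_hz, S = d$psd, df = d$f_hz[1],
                 n_segments = d$n_segments[1]),
            class = "spectrum_psd")
})
names(target) <- gl

cfg <- fit_config(duration = 410, device_lag = 0.060)
starts <- list(c(0.004, 0.8, 0.03), c(0.002, 1.5, 0.015))
fit <- fit_parameters(target, starts, cfg, seed = 11,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 60, ftol = 1e-8, ptol = 1e-8))
print(fit)
print(fit$starts)

jsonlite::write_json(
  list(k_noise_hat = fit$k_noise_hat, tau_noise_hat = fit$tau_noise_hat,
       Te_hat = fit$Te_hat, objective = fit$objective,
       n_evals = fit$n_evals, noise_seed = fit$noise_seed,
       starts = fit$starts),
  "results/fit_result.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Wrote results/fit_result.json")
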