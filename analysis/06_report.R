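#!/usr/bin/env Rscript
# Stage 6 — compare the experiment's sway-versus-gain surface with the
# fitted model's.
#
# Simulates the battery at the stage-5 fitted parameters and tabulates
# integrated position/velocity power per gain next to the synthetic
# experiment's condition means — the model-versus-data comparison
# surface. Requires stages 3 and 5.

suppressPackageStartupMessages(library(hapticsway))
fitj <- jsonlite::read_json("results/fit_result.json",
                            simplifyVector = TRUE)
sc <- read.csv("results/subject_condition_means.csv",
               colClasses = c(condition = "character"))
gl <- format_gain(study_gains())

body <- body_params(); ctrl <- control_params(body)
cp <- conflict_params(Te = fitj$Te_hat)
np0 <- noise_params(fitj$k_noise_hat, fitj$tau_noise_hat)

powers <- function(tr) {
  if (tr$diverged) return(c(pos = NA, vel = NA))
  v <- lowpass_then_differentiate(tr$x_body, fs = tr$fs)
  c(pos = integrate_spectrum(segmented_psd(tr$x_body, tr$fs, discard_s = 10)),
    vel = integrate_spectrum(segmented_psd(v, tr$fs, discard_s = 10)))
}
sim <- sapply(study_gains(), function(g) {
  rowMeans(sapply(1:3, function(s) {
    np <- np0; np$seed <- as.integer(s)
    powers(simulate_trial(body, ctrl, cp, np,
                          gain_condition(g, device_lag = 0.060),
                          duration = 410))
  }), na.rm = TRUE)
})

emp <- function(msr) {
  d <- sc[sc$measure == msr & sc$condition %in% gl, ]
  tapply(d$value, d$condition, mean)[gl]
}
out <- data.frame(gain = study_gains(),
                  pos_power_data = as.numeric(emp("pos_power")),
                  pos_power_model = sim["pos", ],
                  vel_power_data = as.numeric(emp("vel_power")),
                  vel_power_model = sim["vel", ])
write.csv(out, "results/model_vs_data.csv", row.names = FALSE)
message("Integrated power, data vs fitted model, by gain:")
print(out, digits = 3)
message("Wrote results/model_vs_data.csv")
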