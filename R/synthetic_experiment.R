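#' Design of a synthetic haptic-gain experiment
#'
#' Mirrors the study protocol: subjects stand for repeated 50-s trials at
#' each of the nine haptic gains plus a no-touch condition, trunk and
#' robot position sampled at 120 Hz, the first 10 s of every trial
#' discarded from analysis, and the robot tracking the trunk with a 60-ms
#' device lag.
#'
#' @param n_subjects Number of subjects.
#' @param gains Haptic gain grid.
#' @param include_no_touch Append a no-touch condition.
#' @param trials_per_condition Repetitions of each condition.
#' @param trial_s Trial duration (s).
#' @param fs Sampling rate (Hz).
#' @param discard_s Leading settling time (s) flagged for discarding.
#' @param device_lag Body-to-robot latency (s).
#' @param master_seed Seed from which all per-subject/trial seeds derive.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(n_subjects = 14, gains = study_gains(),
                              include_no_touch = TRUE,
                              trials_per_condition = 5, trial_s = 50,
                              fs = 120, discard_s = 10, device_lag = 0.060,
                              master_seed = 1L) {
  conditions <- c(format_gain(gains),
                  if (include_no_touch) "notouch")
  structure(list(n_subjects = as.integer(n_subjects),
                 gains = as.numeric(gains), conditions = conditions,
                 trials_per_condition = as.integer(trials_per_condition),
                 trial_s = as.numeric(trial_s), fs = as.numeric(fs),
                 discard_s = as.numeric(discard_s),
                 device_lag = as.numeric(device_lag),
                 master_seed = as.integer(master_seed)),
            class = "experiment_design")
}

#' Hand-object force-coupling parameters
#'
#' Minimal structure generating plausible light-touch interaction forces:
#' the anterior-posterior force follows relative hand-object displacement
#' through a linear stiffness with a sensorimotor lag, superposed on a
#' static grip baseline and low-pass-filtered sensor noise. Tuned so
#' trial-mean force magnitude stays below ~1 N, peak force-position
#' correlations sit around 0.4-0.7 s lag, and the correlation sign
#' reverses for strongly reversed gain — without claiming grip mechanics.
#'
#' @param stiffness AP force per unit relative displacement (N/m).
#' @param lag_s Force lag behind relative displacement (s); within the
#'   0.4-0.7 s band seen for sensorimotor (not mechanical) coupling.
#' @param baseline Static contact force vector `c(Fx, Fy, Fz)` (N).
#' @param noise_sd Force noise standard deviation per axis (N).
#' @param noise_tau Time constant (s) of the force-noise low-pass.
#' @return A `force_coupling` list.
#' @export
force_coupling_params <- function(stiffness = 12, lag_s = 0.55,
                                  baseline = c(0.10, 0.15, 0.40),
                                  noise_sd = 0.10, noise_tau = 0.1) {
  stopifnot(lag_s > 0, stiffness >= 0, length(baseline) == 3, noise_sd >= 0)
  structure(list(stiffness = as.numeric(stiffness),
                 lag_s = as.numeric(lag_s), baseline = as.numeric(baseline),
                 noise_sd = as.numeric(noise_sd),
                 noise_tau = as.numeric(noise_tau)),
            class = "force_coupling")
}

# low-pass filtered Gaussian noise at the trial rate (force sensor noise)
lp_noise <- function(n, sd, tau, fs) {
  if (sd == 0) return(numeric(n))
  a <- exp(-1 / (tau * fs))
  x <- stats::filter(stats::rnorm(n, sd = sd * sqrt(1 - a^2)), a,
                     method = "recursive")
  as.numeric(x)
}

#' Synthesise triaxial hand forces from relative hand-object motion
#'
#' AP component: `-stiffness * rel_disp` delayed by `lag_s` (leading
#' samples hold the baseline), plus the AP baseline and filtered noise.
#' Off-axis components carry baseline plus noise only.
#'
#' @param rel_disp Relative displacement series `x_robot - x_trunk` (m).
#' @param force A [force_coupling_params()] object.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for the force noise.
#' @return List of series `Fx` (AP), `Fy`, `Fz` (N).
#' @export
synth_hand_force <- function(rel_disp, force = force_coupling_params(), fs,
                             seed = 1L) {
  n <- length(rel_disp)
  lag_n <- as.integer(round(force$lag_s * fs))
  if (lag_n >= n)
    stop("force lag_s is not shorter than the series", call. = FALSE)
  delayed <- c(rep(0, lag_n), rel_disp[seq_len(n - lag_n)])
  set.seed(seed)
  Fx <- -force$stiffness * delayed + force$baseline[1] +
    lp_noise(n, force$noise_sd, force$noise_tau, fs)
  Fy <- force$baseline[2] + lp_noise(n, force$noise_sd, force$noise_tau, fs)
  Fz <- force$baseline[3] + lp_noise(n, force$noise_sd, force$noise_tau, fs)
  list(Fx = Fx, Fy = Fy, Fz = Fz)
}

#' Generate a complete synthetic experiment
#'
#' For each subject, anthropometry and noise gain are jittered around the
#' defaults (log-normal, ~10% body / ~20% noise spread) to produce
#' realistic between-subject dispersion; each trial is then simulated
#' with the closed-loop stance model at its condition's gain (no-touch:
#' touch weight 0), the robot position taken from the lagged gain
#' coupling, and hand forces synthesised from the relative motion. Every
#' seed derives deterministically from `design$master_seed`, so the same
#' design regenerates a byte-identical dataset.
#'
#' @param design An [experiment_design()].
#' @param body,ctrl,cp,np Template model parameters; per-subject values
#'   are jittered from these.
#' @param force A [force_coupling_params()].
#' @param body_jitter_sd,knoise_jitter_sd Log-normal jitter SDs.
#' @return List of `trial_record` objects (see [trial_record()]), with a
#'   `manifest` attribute recording the design and all parameters.
#' @export
generate_dataset <- function(design = experiment_design(),
                             body = body_params(),
                             ctrl = control_params(body),
                             cp = conflict_params(),
                             np = noise_params(),
                             force = force_coupling_params(),
                             body_jitter_sd = 0.1,
                             knoise_jitter_sd = 0.2) {
  records <- list()
  for (i in seq_len(design$n_subjects)) {
    set.seed(design$master_seed + 7919L * i)
    jit <- exp(stats::rnorm(3, sd = c(body_jitter_sd, body_jitter_sd,
                                      knoise_jitter_sd)))
    body_i <- body_params(h = body$h * jit[1], m = body$m * jit[2],
                          J = body$J * jit[1]^2 * jit[2], g = body$g)
    # controller gains scale with the subject's toppling stiffness
    scl <- (body_i$m * body_i$g * body_i$h) / (body$m * body$g * body$h)
    ctrl_i <- control_params(body_i, Kp = ctrl$Kp * scl, Kd = ctrl$Kd * scl,
                             delay = ctrl$delay, w_touch = ctrl$w_touch)
    k_noise_i <- np$k_noise * jit[3]
    subject <- sprintf("S%02d", i)
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      no_touch <- identical(cond, "notouch")
      G <- if (no_touch) 0 else design$gains[ci]
      for (tr_i in seq_len(design$trials_per_condition)) {
        seed_t <- design$master_seed + 100000L * i + 1000L * ci + tr_i
        ctrl_t <- if (no_touch)
          control_params(body_i, Kp = ctrl_i$Kp, Kd = ctrl_i$Kd,
                         delay = ctrl_i$delay, w_touch = 0)
        else ctrl_i
        sim <- simulate_trial(
          body_i, ctrl_t, cp,
          noise_params(k_noise_i, np$tau_noise, seed = seed_t),
          gain_condition(G = G, device_lag = design$device_lag),
          duration = design$trial_s, fs_out = design$fs)
        x_robot <- if (no_touch) rep(0, length(sim$x_body)) else sim$x_robot
        rel <- x_robot - sim$x_body
        F3 <- if (no_touch)
          synth_hand_force(rep(0, length(rel)),
                           force_coupling_params(
                             stiffness = 0, lag_s = force$lag_s,
                             baseline = force$baseline,
                             noise_sd = force$noise_sd,
                             noise_tau = force$noise_tau),
                           design$fs, seed = seed_t + 1L)
        else synth_hand_force(rel, force, design$fs, seed = seed_t + 1L)
        records[[length(records) + 1L]] <- trial_record(
          t = sim$t, x_trunk = sim$x_body, x_robot = x_robot,
          Fx = F3$Fx, Fy = F3$Fy, Fz = F3$Fz, fs = design$fs,
          subject = subject, condition = cond, trial = tr_i)
      }
    }
  }
  attr(records, "manifest") <- list(
    design = unclass(design),
    model = list(body = unclass(body), ctrl = unclass(ctrl),
                 conflict = unclass(cp), noise = unclass(np)),
    force = unclass(force),
    jitter = list(body_sd = body_jitter_sd, k_noise_sd = knoise_jitter_sd))
  records
}
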