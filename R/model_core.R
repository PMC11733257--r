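#' Advance the inverted-pendulum plant one step
#'
#' Semi-implicit Euler update of the linearised pendulum
#' \eqn{J \ddot\theta = m g h \theta - \tau}: the velocity is advanced
#' first and the position with the new velocity. Linear in state and
#' torque. This is the reference single-step form of the integrator used
#' by the compiled closed-loop simulator.
#'
#' @param state Numeric length-2 vector `c(theta, theta_dot)` (rad, rad/s).
#' @param torque Corrective ankle torque (N m).
#' @param body A [body_params()] object.
#' @param dt Time step (s).
#' @return Numeric length-2 vector, the advanced state.
#' @export
plant_step <- function(state, torque, body = body_params(), dt) {
  if (!all(is.finite(state)) || !is.finite(torque))
    stop("non-finite state or torque", call. = FALSE)
  stopifnot(dt > 0)
  theta_dot <- state[2] + dt * (body$m * body$g * body$h * state[1] - torque) / body$J
  theta <- state[1] + dt * theta_dot
  c(theta, theta_dot)
}

#' Per-channel sensory estimates of body angle and velocity
#'
#' The space channel reads body orientation directly; the touch channel
#' reads the horizontal hand-object distance \eqn{s = G x_{del} - x} and
#' converts it to an equivalent body angle, \eqn{\theta_{touch} = -s/h}.
#' The same noise realisation is added to both channels (position value
#' and its derivative to the respective cues).
#'
#' @param theta,theta_dot Body angle (rad) and angular velocity (rad/s).
#' @param gain A [gain_condition()]; with `device_lag = 0` the delayed body
#'   position equals the current one.
#' @param noise_sample Length-2 vector `c(n, n_dot)` of the shared noise.
#' @param body A [body_params()] object.
#' @param theta_delayed,theta_dot_delayed Body state `device_lag` seconds
#'   ago (defaults: current state, i.e. zero lag).
#' @return List with `theta_space`, `thetadot_space`, `theta_touch`,
#'   `thetadot_touch` (rad, rad/s).
#' @export
sensory_estimates <- function(theta, theta_dot, gain = gain_condition(),
                              noise_sample = c(0, 0), body = body_params(),
                              theta_delayed = theta,
                              theta_dot_delayed = theta_dot) {
  if (body$h == 0) stop("body height h must be nonzero", call. = FALSE)
  n <- noise_sample[1]
  n_dot <- noise_sample[2]
  x_body <- body$h * theta
  s <- gain$G * body$h * theta_delayed - x_body
  list(theta_space = theta + n,
       thetadot_space = theta_dot + n_dot,
       theta_touch = -s / body$h + n,
       thetadot_touch = theta_dot - gain$G * theta_dot_delayed + n_dot)
}

#' Conflict-estimator correction
#'
#' Compares touch- and space-derived angular velocity; when the difference
#' `d = v_touch - v_space` exceeds the threshold in magnitude, returns the
#' correction to be subtracted from the touch loop: the full difference
#' (`mode = "literal"`) or the supra-threshold excess (`"deadzone"`).
#' Below threshold the correction is zero.
#'
#' @param v_touch,v_space Velocity cues (rad/s).
#' @param cp A [conflict_params()] object.
#' @return Correction (rad/s).
#' @export
conflict_correction <- function(v_touch, v_space, cp = conflict_params()) {
  d <- v_touch - v_space
  out <- numeric(length(d))
  over <- abs(d) > cp$Te
  if (cp$mode == "literal") out[over] <- d[over]
  else out[over] <- sign(d[over]) * (abs(d[over]) - cp$Te)
  out
}

#' Advance the filtered-noise process one step
#'
#' Forward-Euler step of the first-order low-pass filter
#' \eqn{\dot n = (w - n)/\tau} driven by white noise `w` (standard-normal
#' draw scaled by \eqn{1/\sqrt{dt}}), output gain-scaled by `k_noise`.
#' Returns the scaled value, its analytic derivative and the advanced
#' (unscaled) filter state, so position and velocity cues built from it
#' are mutually consistent.
#'
#' @param state Current unscaled filter state.
#' @param w Standard-normal draw for this step.
#' @param params A [noise_params()] object.
#' @param dt Time step (s).
#' @return List with `n`, `n_dot` (scaled outputs) and `state` (advanced).
#' @export
noise_step <- function(state, w, params = noise_params(), dt) {
  stopifnot(dt > 0)
  if (params$tau_noise <= 0) stop("tau_noise must be positive", call. = FALSE)
  n_dot_state <- (w / sqrt(dt) - state) / params$tau_noise
  list(n = params$k_noise * state,
       n_dot = params$k_noise * n_dot_state,
       state = state + dt * n_dot_state)
}

#' Generate a filtered-noise realisation
#'
#' Vectorised generator for the process advanced by [noise_step()]: `n`
#' standard-normal draws from `seed`, filtered and scaled. Identical seed
#' and parameters give a bit-identical realisation.
#'
#' @param n_steps Number of steps.
#' @param params A [noise_params()] object (its `seed` is used).
#' @param dt Time step (s).
#' @return List with vectors `n` and `n_dot`.
#' @export
filtered_noise <- function(n_steps, params = noise_params(), dt) {
  stopifnot(n_steps >= 1, dt > 0)
  if (params$tau_noise <= 0) stop("tau_noise must be positive", call. = FALSE)
  w <- local({
    set.seed(params$seed)
    rnorm(n_steps)
  })
  filtered_noise_loop(w, dt, params$k_noise, params$tau_noise)
}

#' Simulate one closed-loop stance trial
#'
#' Runs the full model — pendulum plant, delayed PD controller on the
#' weighted channel blend, conflict estimator, shared filtered noise — at a
#' fixed internal step `dt` and returns traces decimated to the analysis
#' rate `fs_out`. Deterministic given `np$seed`. A run whose sway angle
#' exceeds `diverge_limit` is truncated and flagged (`diverged = TRUE`)
#' rather than raising, so instability can be counted in ablations.
#'
#' @param body A [body_params()] object.
#' @param ctrl A [control_params()] object.
#' @param cp A [conflict_params()] object.
#' @param np A [noise_params()] object.
#' @param gain A [gain_condition()] object.
#' @param duration Total simulated time (s), including any settling time
#'   the analysis later discards.
#' @param dt Internal integration step (s); default 1/1200.
#' @param fs_out Output sampling rate (Hz); must divide 1/dt.
#' @param diverge_limit Sway angle (rad) treated as divergence.
#' @return A `sim_trace`: list of aligned series `t`, `theta`, `theta_dot`,
#'   `x_body`, `x_robot`, `theta_touch`, `theta_space`, `conflict`,
#'   `torque`, plus `fs`, `diverged` and the generating parameters.
#' @export
simulate_trial <- function(body = body_params(), ctrl = control_params(body),
                           cp = conflict_params(), np = noise_params(),
                           gain = gain_condition(), duration = 50,
                           dt = 1 / 1200, fs_out = 120,
                           diverge_limit = 0.5) {
  stopifnot(duration >= 50 * dt, dt > 0)
  decim <- 1 / (fs_out * dt)
  if (abs(decim - round(decim)) > 1e-9)
    stop("fs_out must divide the internal rate 1/dt", call. = FALSE)
  decim <- as.integer(round(decim))
  n_steps <- as.integer(round(duration / dt))
  delay_steps <- as.integer(round(ctrl$delay / dt))
  lag_steps <- as.integer(round(gain$device_lag / dt))
  w <- local({
    set.seed(np$seed)
    rnorm(n_steps)
  })
  raw <- sim_core_loop(w, dt, decim,
                       body$h, body$m, body$J, body$g,
                       ctrl$Kp, ctrl$Kd, delay_steps,
                       ctrl$w_touch, ctrl$w_space,
                       cp$Te, identical(cp$mode, "deadzone"),
                       if (is.finite(cp$leak_tau)) 1 / cp$leak_tau else 0,
                       np$k_noise, np$tau_noise,
                       gain$G, lag_steps, diverge_limit)
  n_out <- length(raw$theta)
  structure(list(t = seq_len(n_out) / fs_out - 1 / fs_out,
                 theta = raw$theta, theta_dot = raw$theta_dot,
                 x_body = body$h * raw$theta, x_robot = raw$x_robot,
                 theta_touch = raw$theta_touch, theta_space = raw$theta_space,
                 conflict = raw$conflict, torque = raw$torque,
                 fs = fs_out, diverged = raw$diverged,
                 params = list(body = body, ctrl = ctrl, cp = cp, np = np,
                               gain = gain, duration = duration, dt = dt)),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("sim_trace: %.1f s at %g Hz, G = %g%s; sway RMS = %.3g mrad\n",
              length(x$theta) / x$fs, x$fs, x$params$gain$G,
              if (x$diverged) " [DIVERGED]" else "",
              1000 * stats::sd(x$theta)))
  invisible(x)
}

#' Run the model across a battery of gain conditions
#'
#' One simulation per (gain, seed) pair, with the same seeds reused across
#' gains so condition contrasts share noise realisations. The first
#' `discard_s` seconds of each run are flagged for discarding by the
#' analysis stage.
#'
#' @param body,ctrl,cp,np Model parameter objects (see [simulate_trial()]).
#' @param gains Numeric vector of haptic gains (default: the study grid).
#' @param duration Run duration (s).
#' @param seeds Integer vector of seeds, one run per seed per gain.
#' @param device_lag Robot tracking latency (s) applied to every gain.
#' @param discard_s Settling time (s) the analysis should discard.
#' @param ... Passed on to [simulate_trial()].
#' @return A `condition_battery`: named list (one element per gain) of
#'   lists of `sim_trace`, with attributes `gains`, `seeds`, `discard_s`.
#' @export
run_condition_battery <- function(body = body_params(),
                                  ctrl = control_params(body),
                                  cp = conflict_params(),
                                  np = noise_params(),
                                  gains = study_gains(),
                                  duration = 410, seeds = 1L,
                                  device_lag = 0, discard_s = 10, ...) {
  if (length(gains) == 0) stop("empty gain list", call. = FALSE)
  out <- lapply(gains, function(g) {
    lapply(seeds, function(s) {
      np_s <- np
      np_s$seed <- as.integer(s)
      simulate_trial(body, ctrl, cp, np_s,
                     gain_condition(G = g, device_lag = device_lag),
                     duration = duration, ...)
    })
  })
  names(out) <- format_gain(gains)
  structure(out, gains = gains, seeds = as.integer(seeds),
            discard_s = discard_s, class = "condition_battery")
}

#' Format a gain value as a condition label
#' @param g Numeric gain(s).
#' @return Character label(s), e.g. `"-0.5"`, `"0"`, `"2"`.
#' @export
format_gain <- function(g) {
  vapply(g, function(gi) format(gi, trim = TRUE, drop0trailing = TRUE),
         character(1))
}
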