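#' Anthropometric parameters of the inverted-pendulum body model
#'
#' The standing body is modelled as a linearised single-link inverted
#' pendulum rotating about the ankle. Defaults are standard adult values
#' for centre-of-mass height, body mass and moment of inertia.
#'
#' @param h Centre-of-mass height above the ankle joint (m).
#' @param m Body mass (kg).
#' @param J Moment of inertia about the ankle (kg m^2).
#' @param g Gravitational acceleration (m/s^2); fixed at 9.81.
#' @return An object of class `body_params`.
#' @examples
#' bp <- body_params()
#' bp$m * bp$g * bp$h # gravitational toppling stiffness, N m/rad
#' @export
body_params <- function(h = 0.96, m = 68.5, J = 76.4, g = 9.81) {
  stopifnot(is.numeric(h), h > 0, is.numeric(m), m > 0,
            is.numeric(J), J > 0, g > 0)
  structure(list(h = as.numeric(h), m = as.numeric(m), J = as.numeric(J),
                 g = as.numeric(g)), class = "body_params")
}

#' Delayed PD-controller parameters and sensory channel weights
#'
#' Corrective ankle torque is a proportional-derivative function of the
#' blended body-angle estimate, applied after a lumped feedback delay that
#' aggregates neural conduction, processing and muscle activation. The
#' estimate mixes a space-referenced channel (vestibular/proprioceptive)
#' with a touch-referenced channel; weights sum to 1 and `w_touch = 0`
#' encodes the no-touch condition.
#'
#' Defaults scale with the body: `Kp = 1.5 m g h` (stabilising margin of
#' 50% over the gravitational toppling stiffness) and `Kd = 0.3 Kp` s,
#' within the usual posturography range. The default touch weight 0.175
#' keeps the blended loop stiffness above the toppling stiffness for every
#' gain in the study grid except the fully reversed `G = +2`, whose
#' stability then rests on the conflict estimator — the regime in which
#' the model reproduces the observed gain asymmetry.
#'
#' @param body A [body_params()] object used for the default gains.
#' @param Kp Proportional gain (N m/rad); must exceed `m*g*h`.
#' @param Kd Derivative gain (N m s/rad).
#' @param delay Lumped feedback delay (s).
#' @param w_touch Touch-channel weight in `[0, 1]`; `w_space = 1 - w_touch`.
#' @return An object of class `control_params`.
#' @export
control_params <- function(body = body_params(),
                           Kp = 1.5 * body$m * body$g * body$h,
                           Kd = 0.3 * Kp,
                           delay = 0.15,
                           w_touch = 0.175) {
  stopifnot(Kd >= 0, delay >= 0, w_touch >= 0, w_touch <= 1)
  mgh <- body$m * body$g * body$h
  if (Kp <= mgh)
    stop("Kp (", signif(Kp, 4), ") must exceed m*g*h (", signif(mgh, 4),
         ") to stabilise an inverted pendulum", call. = FALSE)
  structure(list(Kp = as.numeric(Kp), Kd = as.numeric(Kd),
                 delay = as.numeric(delay), w_touch = as.numeric(w_touch),
                 w_space = as.numeric(1 - w_touch)),
            class = "control_params")
}

#' Conflict-estimator parameters
#'
#' The conflict estimator compares the body angular velocity implied by the
#' touch channel with that of the space channel. When the difference exceeds
#' the velocity threshold `Te`, a correction is subtracted from the touch
#' feedback loop, attenuating haptic input attributable to object motion
#' rather than self-motion.
#'
#' Two subtraction conventions are provided: `"literal"` subtracts the full
#' difference once the threshold is exceeded; `"deadzone"` subtracts only
#' the supra-threshold excess. Fitted `Te` values are mode-dependent. The
#' default is `"deadzone"`: the residual sub-threshold feedback it leaves
#' in place is what grades the sway-versus-gain profile monotonically,
#' whereas full subtraction over-corrects strongly reversed gains. The
#' velocity correction is carried into the touch position cue through a
#' leaky integrator with time constant `leak_tau`; the default is a pure
#' integrator (`Inf`), which is required for the correction to hold off a
#' persistent reversed-feedback drift.
#'
#' @param Te Conflict velocity threshold (rad/s); `Inf` disables the
#'   correction entirely, `0` makes it permanent.
#' @param mode `"deadzone"` or `"literal"`.
#' @param leak_tau Leak time constant (s) of the position-cue correction.
#' @return An object of class `conflict_params`.
#' @export
conflict_params <- function(Te = 0.025, mode = c("deadzone", "literal"),
                            leak_tau = Inf) {
  mode <- match.arg(mode)
  stopifnot(Te >= 0, leak_tau > 0)
  structure(list(Te = as.numeric(Te), mode = mode,
                 leak_tau = as.numeric(leak_tau)),
            class = "conflict_params")
}

#' Sensory-noise parameters
#'
#' A single Gaussian white-noise source is low-pass filtered (first order,
#' time constant `tau_noise`) and gain scaled by `k_noise`; the filtered
#' value is added to both channels' position cues and its analytic
#' derivative to both velocity cues, so the cues stay mutually consistent
#' and the noise cancels in the conflict signal. An identical seed yields a
#' bit-identical realisation.
#'
#' @param k_noise Noise gain (rad) applied to the filtered process.
#' @param tau_noise Low-pass filter time constant (s).
#' @param seed Integer RNG seed.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(k_noise = 0.003, tau_noise = 1, seed = 1L) {
  stopifnot(k_noise >= 0, tau_noise > 0)
  structure(list(k_noise = as.numeric(k_noise),
                 tau_noise = as.numeric(tau_noise),
                 seed = as.integer(seed)),
            class = "noise_params")
}

#' Haptic feedback gain condition
#'
#' The robot tracks the body's anterior-posterior marker at programmed gain
#' `G`: `G = 0` is a static object, `G = 1` a free-floating object (no
#' relative hand-body motion), `G > 1` reverses the relative motion and
#' `G < 0` amplifies it in opposition. `device_lag` is the body-to-robot
#' tracking latency (0 by default; 0.060 s matches the physical device).
#'
#' @param G Haptic feedback gain (dimensionless).
#' @param device_lag Body-to-robot latency (s).
#' @return An object of class `gain_condition`.
#' @export
gain_condition <- function(G = 0, device_lag = 0) {
  stopifnot(is.finite(G), device_lag >= 0)
  structure(list(G = as.numeric(G), device_lag = as.numeric(device_lag)),
            class = "gain_condition")
}

#' The study's haptic gain grid
#'
#' Nine gains spanning opposing (negative) through static (0) to
#' co-moving/reversed-feedback (positive) object motion.
#'
#' @return Numeric vector of the nine study gains.
#' @export
study_gains <- function() c(-2, -1, -0.5, -0.25, 0, 0.25, 0.5, 1, 2)

#' @export
print.body_params <- function(x, ...) {
  cat(sprintf("Inverted-pendulum body: h = %g m, m = %g kg, J = %g kg m^2 (m g h = %.1f N m/rad)\n",
              x$h, x$m, x$J, x$m * x$g * x$h))
  invisible(x)
}

#' @export
print.control_params <- function(x, ...) {
  cat(sprintf("PD controller: Kp = %.1f N m/rad, Kd = %.1f N m s/rad, delay = %g s, w_touch = %g\n",
              x$Kp, x$Kd, x$delay, x$w_touch))
  invisible(x)
}
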