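# Frequency-domain analysis of the linear limit (conflict threshold
# disabled, Te = Inf). With both channels veridical (G = 0 or w_touch = 0)
# the closed loop is linear time-invariant apart from the lumped delay, and
# admits closed-form transfer functions against which the time-domain
# simulator can be checked.

char_fun <- function(s, body, ctrl) {
  mgh <- body$m * body$g * body$h
  body$J * s^2 - mgh + (ctrl$Kp + ctrl$Kd * s) * exp(-ctrl$delay * s)
}

char_fun_deriv <- function(s, body, ctrl) {
  2 * body$J * s +
    (ctrl$Kd - ctrl$delay * (ctrl$Kp + ctrl$Kd * s)) * exp(-ctrl$delay * s)
}

#' Characteristic roots of the delayed closed loop
#'
#' Newton iteration on the quasi-polynomial
#' \eqn{J s^2 - m g h + (K_p + K_d s) e^{-\Delta s} = 0} from a grid of
#' complex starting points, returning the de-duplicated converged roots.
#' The delay makes the root set infinite; the grid covers the dominant
#' low-frequency roots that decide stability in practice.
#'
#' @param body A [body_params()] object.
#' @param ctrl A [control_params()] object.
#' @param re_range,im_max Real-part range and maximum imaginary part of the
#'   starting grid (rad/s).
#' @param n_grid Grid points per axis.
#' @return Complex vector of roots, sorted by decreasing real part.
#' @export
characteristic_roots <- function(body = body_params(),
                                 ctrl = control_params(body),
                                 re_range = c(-30, 10), im_max = 60,
                                 n_grid = 15) {
  starts <- outer(seq(re_range[1], re_range[2], length.out = n_grid),
                  1i * seq(0, im_max, length.out = n_grid), `+`)
  roots <- complex(0)
  for (s0 in starts) {
    s <- s0
    ok <- FALSE
    for (it in 1:60) {
      f <- char_fun(s, body, ctrl)
      step <- f / char_fun_deriv(s, body, ctrl)
      s <- s - step
      if (!is.finite(s)) break
      if (abs(step) < 1e-10) { ok <- TRUE; break }
    }
    if (ok && abs(char_fun(s, body, ctrl)) < 1e-6) {
      s <- complex(real = Re(s), imaginary = abs(Im(s)))
      if (!any(abs(roots - s) < 1e-5)) roots <- c(roots, s)
    }
  }
  roots[order(-Re(roots))]
}

#' Startup stability check of the default closed loop
#'
#' Verifies that every dominant characteristic root of the linearised loop
#' (conflict disabled, static object) has negative real part. Called by
#' the battery-level drivers before long runs; aborts with a diagnostic
#' listing the offending roots otherwise.
#'
#' @inheritParams characteristic_roots
#' @param margin Required stability margin on the real part (1/s).
#' @return Invisibly, the dominant root (largest real part).
#' @export
assert_stable <- function(body = body_params(), ctrl = control_params(body),
                          margin = 0) {
  r <- characteristic_roots(body, ctrl)
  if (length(r) == 0)
    stop("stability check failed: no characteristic roots located",
         call. = FALSE)
  if (Re(r[1]) > -margin)
    stop("closed loop unstable for these control parameters: dominant root ",
         format(r[1], digits = 4), " (rad/s); adjust Kp/Kd/delay",
         call. = FALSE)
  invisible(r[1])
}

#' Analytic velocity power spectrum of the linear closed loop
#'
#' One-sided PSD of body angular velocity for the linear limit
#' (`Te = Inf`, `G = 0`), where both channels carry the true state plus
#' the shared noise n: the loop reduces to
#' \deqn{\dot\theta(s) = \frac{-s (K_p + K_d s) e^{-\Delta s}}
#'   {J s^2 - m g h + (K_p + K_d s) e^{-\Delta s}} \, n(s)}
#' with n the unit-spectral-density white noise passed through the
#' first-order low-pass (time constant `tau_noise`) and gain `k_noise`.
#' This frequency-domain route shares no code with the time-stepping
#' simulator and serves as its independent check.
#'
#' @param f Frequency grid (Hz).
#' @param body,ctrl Plant and controller parameters.
#' @param np A [noise_params()] object.
#' @return Numeric vector, one-sided velocity PSD ((rad/s)^2/Hz) on `f`.
#' @export
linear_velocity_psd <- function(f, body = body_params(),
                                ctrl = control_params(body),
                                np = noise_params()) {
  s <- 2i * pi * f
  H <- -s * (ctrl$Kp + ctrl$Kd * s) * exp(-ctrl$delay * s) /
    char_fun(s, body, ctrl)
  S_n <- 2 * np$k_noise^2 / (1 + (2 * pi * f * np$tau_noise)^2)
  Mod(H)^2 * S_n
}
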