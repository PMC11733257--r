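#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop stance simulator: linearised inverted pendulum, delayed PD
// controller fed by a weighted blend of a space-referenced and a
// touch-referenced channel, threshold-based conflict estimator on the
// velocity cues, single low-pass-filtered noise source added to both
// channels (value to position cues, analytic derivative to velocity cues).
//
// Fixed-step semi-implicit Euler at dt; traces recorded every `decim` steps.
// `w` holds standard-normal draws (one per step); internally scaled by
// 1/sqrt(dt) so the driving white noise has unit two-sided spectral density.
//
// Delays are ring buffers of round(delay/dt) steps; history before t = 0 is
// zero (the analysis discards the initial transient).
//
// Divergence (|theta| > diverge_limit) truncates the run and sets a flag
// rather than throwing, so ablation studies can count unstable runs.

// [[Rcpp::export]]
List sim_core_loop(NumericVector w, double dt, int decim,
                   double h, double m, double J, double g,
                   double Kp, double Kd, int delay_steps,
                   double w_touch, double w_space,
                   double Te, bool deadzone, double leak_rate,
                   double k_noise, double tau_noise,
                   double G, int lag_steps,
                   double diverge_limit) {
  const int n_steps = w.size();
  const int n_out_max = (n_steps + decim - 1) / decim;
  const double sigma_w = 1.0 / std::sqrt(dt);

  NumericVector out_theta(n_out_max), out_thetad(n_out_max),
      out_xrobot(n_out_max), out_th_touch(n_out_max), out_th_space(n_out_max),
      out_conflict(n_out_max), out_torque(n_out_max);

  // ring buffers (size >= 1 so modulo is safe)
  const int lag_len = std::max(lag_steps, 1);
  const int del_len = std::max(delay_steps, 1);
  std::vector<double> xb_hist(lag_len, 0.0), thd_hist(lag_len, 0.0);
  std::vector<double> hat_hist(del_len, 0.0), hatd_hist(del_len, 0.0);

  double theta = 0.0, theta_dot = 0.0;
  double n_state = 0.0;  // unscaled low-pass filter state
  double z = 0.0;        // leaky integral of the conflict correction
  bool diverged = false;
  int n_out = 0, k = 0;

  for (k = 0; k < n_steps; ++k) {
    // noise: n' = (w - n)/tau, output scaled by k_noise
    const double wk = w[k] * sigma_w;
    const double n_dot_state = (wk - n_state) / tau_noise;
    const double nv = k_noise * n_state;
    const double ndv = k_noise * n_dot_state;

    // touch geometry: robot follows the body marker at gain G with lag
    const double x_body = h * theta;
    const double x_del = (lag_steps > 0)
        ? ((k >= lag_steps) ? xb_hist[k % lag_len] : 0.0)
        : x_body;
    const double thd_del = (lag_steps > 0)
        ? ((k >= lag_steps) ? thd_hist[k % lag_len] : 0.0)
        : theta_dot;
    const double x_robot = G * x_del;
    const double s_touch = x_robot - x_body;  // hand-object relative position

    // channel estimates (same noise realisation on both)
    const double th_space = theta + nv;
    const double thd_space = theta_dot + ndv;
    const double th_touch = -s_touch / h + nv;       // theta - G*theta_del + n
    const double thd_touch = theta_dot - G * thd_del + ndv;

    // conflict estimator on the velocity cues
    const double d = thd_touch - thd_space;
    double c = 0.0;
    if (std::abs(d) > Te)
      c = deadzone ? (d > 0 ? d - Te : d + Te) : d;
    const double thd_touch_c = thd_touch - c;
    const double th_touch_c = th_touch - z;

    // blended estimate, delayed, into the PD controller
    const double th_hat = w_space * th_space + w_touch * th_touch_c;
    const double thd_hat = w_space * thd_space + w_touch * thd_touch_c;
    const double th_hat_d = (k >= delay_steps) ? hat_hist[k % del_len] : 0.0;
    const double thd_hat_d = (k >= delay_steps) ? hatd_hist[k % del_len] : 0.0;
    const double torque = Kp * th_hat_d + Kd * thd_hat_d;

    if (k % decim == 0) {
      out_theta[n_out] = theta;
      out_thetad[n_out] = theta_dot;
      out_xrobot[n_out] = x_robot;
      out_th_touch[n_out] = th_touch_c;
      out_th_space[n_out] = th_space;
      out_conflict[n_out] = c;
      out_torque[n_out] = torque;
      ++n_out;
    }

    // push histories for time k before advancing
    if (lag_steps > 0) {
      xb_hist[k % lag_len] = x_body;
      thd_hist[k % lag_len] = theta_dot;
    }
    hat_hist[k % del_len] = th_hat;
    hatd_hist[k % del_len] = thd_hat;

    // advance states (semi-implicit Euler for the plant)
    n_state += dt * n_dot_state;
    z += dt * (c - leak_rate * z);
    theta_dot += dt * (m * g * h * theta - torque) / J;
    theta += dt * theta_dot;

    if (!std::isfinite(theta) || std::abs(theta) > diverge_limit) {
      diverged = true;
      ++k;
      break;
    }
  }

  auto trim = [n_out](NumericVector v) {
    return NumericVector(v.begin(), v.begin() + n_out);
  };
  return List::create(
      _["theta"] = trim(out_theta), _["theta_dot"] = trim(out_thetad),
      _["x_robot"] = trim(out_xrobot), _["theta_touch"] = trim(out_th_touch),
      _["theta_space"] = trim(out_th_space), _["conflict"] = trim(out_conflict),
      _["torque"] = trim(out_torque), _["diverged"] = diverged,
      _["steps_completed"] = k);
}

// First-order low-pass filtered, gain-scaled white noise, with the analytic
// derivative of the filter state. Same discretisation as the closed loop.

// [[Rcpp::export]]
List filtered_noise_loop(NumericVector w, double dt, double k_noise,
                         double tau_noise) {
  const int n = w.size();
  const double sigma_w = 1.0 / std::sqrt(dt);
  NumericVector nv(n), ndv(n);
  double n_state = 0.0;
  for (int k = 0; k < n; ++k) {
    const double n_dot = (w[k] * sigma_w - n_state) / tau_noise;
    nv[k] = k_noise * n_state;
    ndv[k] = k_noise * n_dot;
    n_state += dt * n_dot;
  }
  return List::create(_["n"] = nv, _["n_dot"] = ndv);
}
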