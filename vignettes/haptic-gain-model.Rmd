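---
title: "Modelling postural sway under altered haptic feedback gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postural sway under altered haptic feedback gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticsway)
```

## The problem

Lightly gripping a stationary object reduces standing sway, even though
the contact forces (< 1 N) are mechanically irrelevant: the fingertip
acts as a sensor, not a support. When the object is a robot that tracks
the body's own sway at a programmable gain `G`, the haptic feedback can
be amplified (`G < 0`, object moves against the sway), removed (`G = 1`,
object floats with the hand) or reversed (`G = 2`, relative hand-object
motion flips sign). The central nervous system must then decide, moment
by moment, whether hand-object motion reflects self-motion (reafference,
useful for balance) or object motion (exafference, to be ignored).

`hapticsway` implements a closed-loop stance model built around exactly
that decision, the signal pipeline used to quantify sway, repeated-
measures inference over conditions, a spectral fitting layer for the
model's free parameters, and a synthetic-experiment generator that stands
in for the (unavailable) human dataset.

## The model

The body is a linearised single-link inverted pendulum about the ankle,

$$J\,\ddot\theta = m g h\,\theta - \tau(t),$$

with Table-like anthropometric defaults `h = 0.96` m, `m = 68.5` kg,
`J = 76.4` kg m² (`body_params()`), so the gravitational toppling
stiffness is `mgh ≈ 645` N m/rad. Corrective torque is produced by a
proportional–derivative controller acting on a delayed estimate of body
angle and angular velocity:

$$\tau(t) = K_p\,\hat\theta(t-\Delta) + K_d\,\dot{\hat\theta}(t-\Delta),$$

where `Δ` is a lumped delay aggregating conduction, processing and
muscle activation. The estimate blends two sensory channels,

$$\hat\theta = w_{space}\,\theta_{space} + w_{touch}\,\theta_{touch},$$

a *space* channel (vestibular/proprioceptive body-in-space orientation)
and a *touch* channel derived from the horizontal hand-object distance
`s = G\,x(t-\ell) - x(t)` (with `ℓ` the robot's tracking latency),
converted to an equivalent body angle `θ_touch = −s/h`. With a static
object (`G = 0`) the two channels agree; any `G ≠ 0` makes the touch
channel report a distorted gain `1 − G` on true sway.

**The conflict estimator** is the model's core. The velocity difference
between channels, `d = θ̇_touch − θ̇_space`, equals `−G·θ̇` and is
therefore a pure exafference signal. When `|d|` exceeds a threshold `Te`
a correction is subtracted from the touch loop; below threshold the
(possibly distorted) touch feedback is accepted as self-motion. Two
subtraction conventions are implemented (`conflict_params(mode = )`):
`"literal"` removes the full difference and `"deadzone"` only the
supra-threshold excess `sign(d)(|d| − Te)`. The velocity correction is
also integrated (optionally with leak `leak_tau`) and subtracted from
the touch *position* cue, so persistent object motion does not bias the
internal position reference.

**Noise.** Sway is driven by a single Gaussian white-noise source,
first-order low-pass filtered (time constant `tau_noise`) and scaled by
`k_noise`; the filtered value is added to both channels' position cues
and its analytic derivative to both velocity cues. One source on both
channels means the noise cancels inside the conflict signal `d`, which
is exactly what makes `d` an exafference detector; the analytic
derivative avoids spurious conflicts that numerical differentiation of
noise would create.

## Default parameters and why

| parameter | default | meaning |
|---|---|---|
| `Kp` | `1.5·mgh` ≈ 968 N m/rad | proportional gain; must exceed `mgh` |
| `Kd` | `0.3·Kp` s | derivative gain |
| `delay` | 0.15 s | lumped feedback delay |
| `w_touch` | 0.175 | touch weight while touching (0 = no-touch) |
| `Te` | 0.025 rad/s | conflict velocity threshold |
| `mode` | `"deadzone"` | subtraction convention |
| `leak_tau` | `Inf` (pure integrator) | position-cue correction |
| `k_noise` | 0.003 rad | noise gain |
| `tau_noise` | 1 s | noise filter constant |

The controller/weight pair was chosen so that the *blended* loop
stiffness `(w_{space} + w_{touch}(1-G))\,K_p` exceeds `mgh` for every
study gain except `G = +2`. That places the fully reversed condition —
and only that condition — beyond the reach of the linear loop, so its
stability rests on the conflict estimator: with the estimator disabled
(`Te = Inf`) a `G = +2` run diverges, with it enabled the run is bounded
but much larger than at `G = 0`. This is the regime in which the model
reproduces the experimentally observed asymmetry (sway roughly flat to
slightly decreasing over negative gains, rising steeply over positive
ones, maximal at `+2`).

Three defaults deserve their own justification, because the design was
genuinely open:

* **Deadzone subtraction.** With full (`"literal"`) subtraction, a
  supra-threshold conflict instantly restores veridical feedback, and it
  does so *more often* at `G = +2` than at `+1` (the conflict signal
  scales with `|G|`). The result is a non-monotone profile with `+2`
  *less* swaying than `+1`, contrary to the asymmetric surface the model
  is meant to produce. The deadzone leaves a bounded residual error in
  place, grading the correction smoothly with `|G|`; both position and
  velocity power then decrease monotonically from `+2` to `−2`. Fitted
  `Te` values are convention-dependent and must be compared within one
  mode.
* **Pure integration of the position correction.** Holding off a
  *persistent* reversed-gain drift requires the integrated correction to
  retain its value; any finite leak (we examined 10–240 s) lets the
  reference decay between supra-threshold episodes and `G ≥ +1` runs
  eventually diverge. The cost is a slow random-walk component in the
  touch reference, visible as a few-percent inflation of
  lowest-frequency position power at strongly negative gains.
* **Noise scale.** `k_noise` and `tau_noise` are free (fitted)
  parameters; their defaults were set once so that a `G = 0` simulation
  produces eyes-closed-realistic quiet stance — trunk position RMS about
  6 mm with spectral power concentrated below 1 Hz — and kept fixed
  thereafter.

A start-up stability check (`assert_stable()`) locates the dominant
characteristic roots of the delayed quasi-polynomial
`J s² − mgh + (K_p + K_d s)e^{−Δs}` by Newton iteration from a complex
grid and refuses to run batteries with an unstable linearised loop.

## Numerics

The loop is integrated by fixed-step semi-implicit Euler at
`dt = 1/1200` s — ten times the 120-Hz sensor rate — with the feedback
delay and device lag implemented as ring buffers of `round(delay/dt)`
steps, and traces decimated to 120 Hz for analysis so simulated and
"measured" series share a sampling rate. The integrator is first-order;
on the torque-free falling pendulum it tracks the `cosh` closed form to
about 0.1% over half a second at this step, and the unit tests assert
both that bound and the first-order convergence rate. Runs whose sway
angle exceeds 0.5 rad are truncated and *flagged* (`diverged = TRUE`)
rather than raising, so ablation studies can count instability;
the fitting objective maps such runs to large constant penalty residuals
(`1000 × max(target)`).

## The empirical pipeline

Sway magnitude is the integrated one-sided power spectral density of
trunk position and velocity over 0.025–4 Hz. Velocity is obtained by
differentiating position after a second-order 5-Hz Butterworth low-pass,
applied forward–backward (zero phase) with odd-reflection padding to
suppress edge transients; differentiation is by central differences.
Spectra are mean-removed rectangular periodograms over consecutive 40-s
segments, averaged — the simplest estimator consistent with a 0.025-Hz
grid; trials contribute their post-discard 40 s each, long simulations
seventy segments. Parseval holds exactly per segment, which the tests
exploit. Hand force is summarised by the trial-mean Euclidean norm of
the three force components. Hand-force/body-position coupling uses the
unbiased normalised cross-correlation
`R(τ) = Σ x(t) y(t+τ) / (N−|k|) / (σ_x σ_y)`; the reported peak is the
extremum of `|R|` (signed value returned, since reversed gain flips the
sign), with ties resolved to the smallest then positive lag.

Model traces are angles and empirical series positions; the conversion
`x = hθ` is applied once at the comparison boundary, never inside the
metrics.

## Inference

Condition-level effects use the classical one-way repeated-measures
ANOVA (subject a random block; `F = MS_condition/MS_error` on
`(k−1, (k−1)(n−1))` degrees of freedom, reported uncorrected as is
conventional for this literature, with a Greenhouse–Geisser-corrected p
attached as a labelled extra) and Tukey-corrected pairwise comparisons
via the studentized range on the ANOVA error term. Sway-power measures
are tested over all ten conditions (df 9, 117 at the study's size);
force and coupling measures over the nine touch conditions (df 8, 104).

## Fitting

The three free parameters are estimated by bounded Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`) on log-parameters, minimising
`Σ_{g,f} (S_target(g,f) − S_sim(g,f))² / f` over the 160 bins of
0.025–4 Hz and the nine gain conditions, velocity spectra only. Each
evaluation re-simulates the battery with the *same* seed, so the
objective is deterministic and has an exact zero at the generating
parameters when the seed matches. Multi-start behaviour is recorded in
the result (`fit$starts`) as a basin diagnostic rather than asserted.
The routine protocol simulates 410 s per condition (ten spectral
segments after the 10-s discard); the full-resolution 2810-s protocol
(seventy segments) is available via `fit_config(duration = 2810)`.
Matched-seed recovery is exact to optimizer precision; with a fresh
noise realisation at 410 s, recovery errors are typically within ~20%
for `k_noise` and `tau_noise` and ~30% for `Te`, the noise gain and
filter constant being partially confounded through the `k/τ` ratio at
mid frequencies.

## The synthetic experiment

`generate_dataset()` emulates the study design — 14 subjects, nine gains
`{−2, −1, −0.5, −0.25, 0, 0.25, 0.5, 1, 2}` plus no-touch, five 50-s
trials per condition at 120 Hz, first 10 s discarded, robot tracking the
trunk with a 60-ms device lag. Subjects get log-normal jitter
(±10% body dimensions with controller gains rescaled to their toppling
stiffness, ±20% noise gain); every trial seed derives from the master
seed, so a manifest regenerates the dataset byte-identically. Hand
force is synthesised as a delayed linear coupling: AP force
`−stiffness × (x_robot − x_trunk)` lagged 0.55 s, on a static grip
baseline with low-pass sensor noise; off-axis channels carry baseline
and noise only. The defaults (12 N/m, 0.10 N noise) keep trial-mean
`|F|` under 1 N in ≥99% of trials, put condition-mean peak correlations
around 0.4–0.85 with lags inside 0.4–0.7 s for well-coupled gains, and
reverse the correlation sign at `G = +2` — the three qualitative force
facts the generator is contracted to reproduce.

What the generator does *not* emulate: no-touch trials use the same
noise level as touch trials, so the synthetic dataset shows no
touch-induced sway reduction relative to no-touch (in humans that
reduction is 55–62%; reproducing it would require asserting how touch
changes sensory precision, which the model does not claim); there is no
medio-lateral axis, no grip mechanics, and no claim about absolute human
sway magnitudes. Tests passing on synthetic data therefore validate the
*pipeline and model mechanics*, not human effect sizes.

## Problem sizes used by the checks

The routine checks simulate 410-s batteries (three matched seeds),
pool three 2810-s runs for the linear-limit comparison, and run the
synthetic experiment at two trials per condition (280 trials); these
sizes put Monte-Carlo noise comfortably below the tolerances asserted
while keeping the whole suite at a couple of minutes.

## Known limitations

* At `G = +2` with default parameters, very long runs (2810 s) can
  occasionally diverge: the conflict-bounded instability escapes roughly
  once per hour of simulated time. The 410-s protocol is stable across
  seeds; the fitting objective treats divergence with penalty residuals.
* The linear-limit oracle compares band integrals; single 0.025-Hz bins
  carry chi-squared estimator noise and rectangular-window leakage
  (prominent exactly where the velocity spectrum rises steeply from its
  lowest bins).
* Uncertainty on fitted parameters is characterised only by
  multi-realisation dispersion; no covariance or profile likelihood is
  attempted.
* The plant/controller parameters are fixed, not fitted: closed-loop
  sway spectra alone cannot identify them without external perturbation
  experiments.
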