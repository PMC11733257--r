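test_that("plant at equilibrium stays exactly at equilibrium", {
  st <- c(0, 0)
  for (i in 1:100) st <- plant_step(st, 0, default_body, dt = 1 / 1200)
  expect_identical(st, c(0, 0))
})

test_that("plant step matches the linearised angular acceleration", {
  dt <- 1 / 1200
  st <- plant_step(c(0.01, 0), 0, default_body, dt)
  accel <- with(default_body, m * g * h * 0.01 / J)
  expect_equal(st[2], accel * dt, tolerance = 1e-12)
})

test_that("torque-free fall matches the closed-form cosh solution", {
  theta0 <- 0.02
  lambda <- with(default_body, sqrt(m * g * h / J))
  exact <- theta0 * cosh(lambda * 0.5)
  fall <- function(dt) {
    st <- c(theta0, 0)
    for (i in seq_len(round(0.5 / dt))) st <- plant_step(st, 0,
                                                         default_body, dt)
    st[1]
  }
  err <- abs(fall(1 / 1200) / exact - 1)
  expect_lt(err, 2e-3)
  # the semi-implicit update is first-order: halving dt halves the error
  err2 <- abs(fall(1 / 2400) / exact - 1)
  expect_equal(err2 / err, 0.5, tolerance = 0.1)
})

test_that("plant step rejects non-finite inputs", {
  expect_error(plant_step(c(NaN, 0), 0, default_body, 1 / 120), "non-finite")
  expect_error(plant_step(c(0, 0), Inf, default_body, 1 / 120), "non-finite")
})

test_that("sensory estimates reproduce the gain geometry", {
  # static object: touch reads true sway
  se <- sensory_estimates(0.01, 0.002, gain_condition(G = 0))
  expect_equal(se$theta_touch, 0.01)
  expect_equal(se$thetadot_touch, 0.002)
  # free-floating object (G = 1, no lag): touch carries noise only
  se <- sensory_estimates(0.01, 0.002, gain_condition(G = 1),
                          noise_sample = c(3e-4, 1e-4))
  expect_equal(se$theta_touch, 3e-4)
  expect_equal(se$thetadot_touch, 1e-4)
  # G = 2: sign-reversed feedback
  se <- sensory_estimates(0.01, 0.002, gain_condition(G = 2))
  expect_equal(se$theta_touch, -0.01)
  expect_equal(se$thetadot_touch, -0.002)
})

test_that("conflict correction thresholds and both subtraction modes work", {
  lit <- conflict_params(Te = 0.05, mode = "literal")
  expect_equal(conflict_correction(0.10, 0.08, lit), 0)
  lit <- conflict_params(Te = 0.10, mode = "literal")
  expect_equal(conflict_correction(0.30, 0.05, lit), 0.25)
  dz <- conflict_params(Te = 0.10, mode = "deadzone")
  expect_equal(conflict_correction(0.30, 0.05, dz), 0.15)
  # symmetric for negative differences
  expect_equal(conflict_correction(0.05, 0.30, lit), -0.25)
  expect_equal(conflict_correction(0.05, 0.30, dz), -0.15)
})

test_that("filtered noise is reproducible and zero at zero gain", {
  dt <- 1 / 1200
  z <- filtered_noise(1000, noise_params(k_noise = 0, seed = 3), dt)
  expect_true(all(z$n == 0) && all(z$n_dot == 0))
  a <- filtered_noise(1000, noise_params(seed = 11), dt)
  b <- filtered_noise(1000, noise_params(seed = 11), dt)
  expect_identical(a, b)
  c2 <- filtered_noise(1000, noise_params(seed = 12), dt)
  expect_false(identical(a$n, c2$n))
})

test_that("noise stationary variance matches the AR(1) closed form", {
  dt <- 1 / 1200
  np <- noise_params(k_noise = 0.01, tau_noise = 0.5, seed = 7)
  z <- filtered_noise(1.2e6, np, dt)
  burn <- round(20 * np$tau_noise / dt)
  v_obs <- stats::var(z$n[-seq_len(burn)])
  # Euler-discretised filter: n[k+1] = a n[k] + b w[k], w ~ N(0, 1/dt)
  a <- 1 - dt / np$tau_noise
  b <- dt / np$tau_noise
  v_exp <- np$k_noise^2 * b^2 * (1 / dt) / (1 - a^2)
  expect_equal(v_obs, v_exp, tolerance = 0.02)
})

test_that("noise_step single-step contract matches the vectorised generator", {
  dt <- 1 / 1200
  np <- noise_params(k_noise = 0.004, tau_noise = 0.8, seed = 21)
  w <- local({ set.seed(np$seed); rnorm(50) })
  st <- 0
  n_r <- n_dot_r <- numeric(50)
  for (i in 1:50) {
    stp <- noise_step(st, w[i], np, dt)
    n_r[i] <- stp$n; n_dot_r[i] <- stp$n_dot; st <- stp$state
  }
  z <- filtered_noise(50, np, dt)
  expect_equal(n_r, z$n, tolerance = 1e-12)
  expect_equal(n_dot_r, z$n_dot, tolerance = 1e-12)
})

test_that("zero noise gives identically zero sway", {
  for (g in c(-2, 0, 2)) {
    tr <- simulate_trial(np = noise_params(k_noise = 0),
                         gain = gain_condition(g), duration = 50)
    expect_identical(max(abs(tr$theta)), 0)
  }
})

test_that("simulated traces satisfy their structural invariants", {
  tr <- simulate_trial(np = noise_params(seed = 5),
                       gain = gain_condition(0.5, device_lag = 0.06),
                       duration = 60)
  n <- length(tr$t)
  for (s in c("theta", "theta_dot", "x_body", "x_robot", "theta_touch",
              "theta_space", "conflict", "torque"))
    expect_length(tr[[s]], n)
  expect_equal(tr$x_body, default_body$h * tr$theta)
  expect_false(tr$diverged)
  # determinism
  tr2 <- simulate_trial(np = noise_params(seed = 5),
                        gain = gain_condition(0.5, device_lag = 0.06),
                        duration = 60)
  expect_identical(tr$theta, tr2$theta)
})

test_that("free-floating gain degenerates to a noise-only touch channel", {
  # G = 1 without device lag: the touch position cue carries only noise,
  # so theta_touch (uncorrected, Te = Inf) equals theta_space - theta
  tr <- simulate_trial(cp = conflict_params(Te = Inf),
                       np = noise_params(seed = 9),
                       gain = gain_condition(1), duration = 50)
  expect_equal(tr$theta_touch, tr$theta_space - tr$theta, tolerance = 1e-12)
})

test_that("divergence is flagged, not raised", {
  tr <- simulate_trial(cp = conflict_params(Te = Inf),
                       np = noise_params(seed = 1),
                       gain = gain_condition(2), duration = 410)
  expect_true(tr$diverged)
  expect_lt(length(tr$theta), 410 * 120)
})

test_that("condition battery covers the study grid deterministically", {
  bat <- run_condition_battery(np = noise_params(), duration = 50,
                               seeds = c(1, 2))
  expect_length(bat, 9)
  expect_named(bat, format_gain(study_gains()))
  expect_length(bat[["0"]], 2)
  bat2 <- run_condition_battery(np = noise_params(), duration = 50,
                                seeds = c(1, 2))
  expect_identical(bat[["-2"]][[1]]$theta, bat2[["-2"]][[1]]$theta)
  expect_error(run_condition_battery(gains = numeric(0)), "empty")
})

test_that("integrated velocity power is stable across noise realisations", {
  pows <- sapply(1:3, function(s) {
    tr <- simulate_trial(np = noise_params(seed = s), duration = 2810)
    trace_powers(tr)["vel"]
  })
  expect_lt(stats::sd(pows) / mean(pows), 0.15)
})

test_that("a permanent conflict correction reduces to the no-touch loop", {
  ctrl0 <- control_params(default_body, Kp = default_ctrl$Kp,
                          Kd = default_ctrl$Kd, delay = default_ctrl$delay,
                          w_touch = 0)
  for (g in c(-1, 2)) {
    a <- rowMeans(sapply(1:3, function(s) trace_powers(
      simulate_trial(default_body, default_ctrl,
                     conflict_params(Te = 0), noise_params(seed = s),
                     gain_condition(g), duration = 410))))
    b <- rowMeans(sapply(1:3, function(s) trace_powers(
      simulate_trial(default_body, ctrl0, conflict_params(Te = 0),
                     noise_params(seed = s),
                     gain_condition(g), duration = 410))))
    expect_equal(a[["pos"]], b[["pos"]], tolerance = 0.2)
    expect_equal(a[["vel"]], b[["vel"]], tolerance = 0.2)
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(body_params(h = -1))
  expect_error(control_params(default_body, Kp = 100), "must exceed")
  expect_error(conflict_params(Te = -0.1))
  expect_error(noise_params(tau_noise = 0))
  expect_error(gain_condition(G = Inf))
})
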