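test_that("filter-then-differentiate handles constants and ramps", {
  fs <- 120
  expect_equal(lowpass_then_differentiate(rep(2.5, 600), fs),
               rep(0, 600), tolerance = 1e-9)
  x <- 0.03 * seq_len(600) / fs
  v <- lowpass_then_differentiate(x, fs)
  expect_equal(v[100:500], rep(0.03, 401), tolerance = 1e-6)
  expect_error(lowpass_then_differentiate(c(1, 2), fs), "3 samples")
  expect_error(lowpass_then_differentiate(rep(1, 10), fs = 8), "fs > 2")
})

test_that("sine attenuation matches an independent frequency response", {
  fs <- 120; f0 <- 1
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  v <- lowpass_then_differentiate(sin(2 * pi * f0 * t), fs)
  # independent route: evaluate the digital filter polynomials at e^{iw};
  # zero-phase application squares the magnitude, central difference
  # contributes fs*sin(w/fs)
  bf <- signal::butter(2, 5 / (fs / 2))
  z <- exp(-1i * 2 * pi * f0 / fs)
  H <- sum(bf$b * z^(0:2)) / sum(bf$a * z^(0:2))
  amp_exp <- Mod(H)^2 * fs * sin(2 * pi * f0 / fs)
  interior <- v[(5 * fs):(115 * fs)]
  expect_equal(sqrt(2 * mean(interior^2)), amp_exp, tolerance = 1e-4)
})

test_that("segmented PSD resolves a pure tone with Parseval-exact power", {
  fs <- 120; A <- 0.7
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  sp <- segmented_psd(A * sin(2 * pi * 0.5 * t), fs)
  expect_equal(sp$df, 0.025)
  expect_equal(sp$f[1], 0.025)
  expect_equal(sum(sp$f >= 0.025 - 1e-9 & sp$f <= 4 + 1e-9), 160)
  peak <- which.max(sp$S)
  expect_equal(sp$f[peak], 0.5)
  expect_equal(integrate_spectrum(sp), A^2 / 2, tolerance = 1e-6)
  # all other bins empty
  expect_lt(sum(sp$S[-peak]) * sp$df, 1e-12)
})

test_that("segmented PSD satisfies Parseval on stationary noise", {
  fs <- 120
  set.seed(42)
  x <- rnorm(70 * 40 * fs, sd = 2)
  sp <- segmented_psd(x, fs)
  total <- sum(sp$S) * sp$df
  # exact identity against the mean per-segment variance
  segs <- matrix(x, nrow = 40 * fs)
  v_seg <- mean(apply(segs, 2, function(s) mean((s - mean(s))^2)))
  expect_equal(total, v_seg, tolerance = 1e-10)
  # Monte-Carlo agreement with the nominal variance
  expect_equal(total, 4, tolerance = 0.05)
})

test_that("segmented PSD pools trial lists and applies discards", {
  fs <- 120
  set.seed(1)
  trials <- replicate(5, rnorm(50 * fs), simplify = FALSE)
  sp <- segmented_psd(trials, fs, discard_s = 10)
  expect_equal(sp$n_segments, 5L)
  expect_error(segmented_psd(rnorm(100), fs), "no full segment")
})

test_that("band integration sums bins times bin width", {
  sp <- structure(list(f = 0.025 * (1:160), S = rep(2, 160), df = 0.025,
                       n_segments = 1L), class = "spectrum_psd")
  expect_equal(integrate_spectrum(sp), 8)
  sp$S <- rep(0, 160)
  expect_equal(integrate_spectrum(sp), 0)
  sp$S[40] <- 5 / 0.025
  expect_equal(integrate_spectrum(sp, 1, 1), 5)
  expect_error(integrate_spectrum(sp, 10, 11), "empty")
})

test_that("force magnitude is the elementwise Euclidean norm", {
  fm <- force_magnitude(3, 4, 0)
  expect_equal(fm$magnitude, 5)
  expect_equal(force_magnitude(0, 0, 0)$mean, 0)
  set.seed(2)
  Fx <- rnorm(200); Fy <- rnorm(200); Fz <- rnorm(200)
  fm <- force_magnitude(Fx, Fy, Fz)
  oracle <- vapply(seq_len(200), function(i)
    sqrt(Fx[i]^2 + Fy[i]^2 + Fz[i]^2), numeric(1))
  expect_equal(fm$magnitude, oracle, tolerance = 1e-12)
  expect_equal(fm$mean, mean(oracle), tolerance = 1e-12)
})

test_that("cross-correlation recovers known delays and inversions", {
  fs <- 120
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(2000), rep(1, 20) / 20, sides = 1))
  x[is.na(x)] <- 0
  y <- c(rep(0, 60), x[1:(2000 - 60)])  # x precedes y by 0.5 s
  r <- xcorr_unbiased(x, y, fs, maxlag = 2)
  pk <- peak_xcorr(r)
  expect_equal(pk$peak_lag, 0.5, tolerance = 1 / fs)
  expect_gt(pk$peak_R, 0.95)
  r2 <- xcorr_unbiased(x, -x, fs, maxlag = 2)
  pk2 <- peak_xcorr(r2)
  expect_equal(pk2$peak_R, -1, tolerance = 1e-10)
  expect_equal(pk2$peak_lag, 0)
})

test_that("cross-correlation equals the brute-force unbiased sum", {
  fs <- 100
  set.seed(4)
  x <- rnorm(1000); y <- rnorm(1000)
  r <- xcorr_unbiased(x, y, fs, maxlag = 0.5)
  o <- xcorr_oracle(x, y, fs, maxlag = 0.5)
  expect_equal(r$lags, o$lags)
  expect_equal(r$R, o$R, tolerance = 1e-10)
})

test_that("cross-correlation symmetry and autocorrelation normalisation", {
  fs <- 50
  set.seed(5)
  x <- rnorm(400); y <- rnorm(400)
  rxy <- xcorr_unbiased(x, y, fs, maxlag = 1)
  ryx <- xcorr_unbiased(y, x, fs, maxlag = 1)
  expect_equal(rxy$R, rev(ryx$R), tolerance = 1e-12)
  rxx <- xcorr_unbiased(x, x, fs, maxlag = 1)
  expect_equal(rxx$R[rxx$lags == 0], 1, tolerance = 1e-12)
  expect_error(xcorr_unbiased(rep(1, 100), rnorm(100), fs), "zero-variance")
})

test_that("peak extraction breaks ties toward small then positive lags", {
  r <- structure(list(lags = c(-1, 0, 1), R = c(0.5, 0.2, 0.5), fs = 1),
                 class = "xcorr_result")
  expect_equal(peak_xcorr(r)$peak_lag, 1)
  r$R <- c(0.5, 0.5, 0.2)
  expect_equal(peak_xcorr(r)$peak_lag, 0)
  r$R <- c(-0.6, 0.5, 0.2)
  pk <- peak_xcorr(r)
  expect_equal(pk$peak_R, -0.6)
  expect_equal(pk$peak_lag, -1)
})
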