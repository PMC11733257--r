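# Shared small fixtures; everything is generated in code.

default_body <- body_params()
default_ctrl <- control_params(default_body)

# integrated 0.025-4 Hz power of position and velocity for one trace,
# through the empirical pipeline
trace_powers <- function(tr, discard_s = 10) {
  if (tr$diverged) return(c(pos = Inf, vel = Inf))
  v <- lowpass_then_differentiate(tr$x_body, fs = tr$fs)
  c(pos = integrate_spectrum(segmented_psd(tr$x_body, tr$fs,
                                           discard_s = discard_s)),
    vel = integrate_spectrum(segmented_psd(v, tr$fs,
                                           discard_s = discard_s)))
}

# condition-mean powers over a battery (matched seeds across gains)
battery_powers <- function(gains, seeds, duration = 410, cp = conflict_params(),
                           ctrl = default_ctrl, np = noise_params()) {
  res <- sapply(gains, function(g) {
    rowMeans(sapply(seeds, function(s) {
      np_s <- np; np_s$seed <- as.integer(s)
      trace_powers(simulate_trial(default_body, ctrl, cp, np_s,
                                  gain_condition(g), duration = duration))
    }))
  })
  colnames(res) <- format_gain(gains)
  res
}

# brute-force O(N^2) unbiased normalised cross-correlation oracle
xcorr_oracle <- function(x, y, fs, maxlag) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
  kmax <- min(round(maxlag * fs), n - 1)
  k <- -kmax:kmax
  R <- vapply(k, function(ki) {
    if (ki >= 0) s <- sum(x[1:(n - ki)] * y[(1 + ki):n])
    else s <- sum(x[(1 - ki):n] * y[1:(n + ki)])
    s / (n - abs(ki)) / (sx * sy)
  }, numeric(1))
  list(lags = k / fs, R = R)
}

# explicit sum-of-squares decomposition for the within-subject one-way design
rm_anova_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  list(F = (ss_cond / df1) / (ss_err / df2), df1 = df1, df2 = df2,
       MS_error = ss_err / df2)
}
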