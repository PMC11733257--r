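#' Low-pass filter then differentiate a position series
#'
#' Applies a second-order Butterworth low-pass (default cutoff 5 Hz) in
#' zero-phase (forward-backward) form, then central-difference
#' differentiation; endpoints use one-sided differences. This is the
#' velocity pipeline applied to trunk-position signals before spectral
#' analysis. A causal (single-pass) variant is available.
#'
#' @param x Position series.
#' @param fs Sampling rate (Hz).
#' @param fc Cutoff frequency (Hz); requires `fs > 2*fc`.
#' @param order Filter order.
#' @param zero_phase Apply the filter forward-backward (default) or once.
#' @return Velocity series, same length as `x`.
#' @export
lowpass_then_differentiate <- function(x, fs, fc = 5, order = 2,
                                       zero_phase = TRUE) {
  if (length(x) < 3) stop("series shorter than 3 samples", call. = FALSE)
  stopifnot(fs > 2 * fc)
  bf <- signal::butter(order, fc / (fs / 2))
  # odd-reflection padding suppresses the zero-state edge transient
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * fs / fc))
  x0 <- x[1]; x1 <- x[n]
  xp <- c(2 * x0 - x[(pad + 1):2], x, 2 * x1 - x[(n - 1):(n - pad)]) - x0
  xf <- if (zero_phase) signal::filtfilt(bf, xp)
        else as.numeric(signal::filter(bf, xp))
  xf <- xf[(pad + 1):(pad + n)] + x0
  n <- length(xf)
  v <- numeric(n)
  v[2:(n - 1)] <- (xf[3:n] - xf[1:(n - 2)]) * fs / 2
  v[1] <- (xf[2] - xf[1]) * fs
  v[n] <- (xf[n] - xf[n - 1]) * fs
  v
}

#' Segment-averaged power spectral density
#'
#' Cuts the series into consecutive non-overlapping segments of
#' `segment_s` seconds (default 40 s, giving 0.025-Hz resolution at any
#' rate), removes each segment's mean, and averages the one-sided
#' rectangular-window periodograms. Each segment's periodogram satisfies
#' Parseval: the sum of the PSD over all bins times the bin width equals
#' the segment's variance.
#'
#' @param x Series, or a list of series (e.g. repeated trials) whose
#'   segments are pooled into one average.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length (s).
#' @param discard_s Leading time (s) dropped from each series before
#'   segmentation.
#' @return A `spectrum_psd`: list with `f` (Hz, starting at one bin width),
#'   `S` (one-sided PSD, unit^2/Hz), `df`, `n_segments`.
#' @export
segmented_psd <- function(x, fs, segment_s = 40, discard_s = 0) {
  if (!is.list(x)) x <- list(x)
  nseg_samp <- as.integer(round(segment_s * fs))
  if (abs(nseg_samp - segment_s * fs) > 1e-6)
    stop("segment_s * fs must be an integer number of samples", call. = FALSE)
  drop_n <- as.integer(round(discard_s * fs))
  acc <- NULL
  n_segments <- 0L
  for (xi in x) {
    xi <- as.numeric(xi)
    if (drop_n > 0) xi <- xi[-seq_len(min(drop_n, length(xi)))]
    k <- length(xi) %/% nseg_samp
    if (k < 1) next
    for (j in seq_len(k)) {
      seg <- xi[((j - 1) * nseg_samp + 1):(j * nseg_samp)]
      seg <- seg - mean(seg)
      X <- stats::fft(seg)
      # one-sided PSD: double all bins except DC and (even n) Nyquist
      half <- nseg_samp %/% 2
      P <- Mod(X[2:(half + 1)])^2 / (fs * nseg_samp)
      scale2 <- rep(2, half)
      if (nseg_samp %% 2 == 0) scale2[half] <- 1
      P <- P * scale2
      acc <- if (is.null(acc)) P else acc + P
      n_segments <- n_segments + 1L
    }
  }
  if (n_segments == 0L)
    stop("no full segment available after discards", call. = FALSE)
  df <- 1 / segment_s
  structure(list(f = df * seq_along(acc), S = acc / n_segments,
                 df = df, n_segments = n_segments),
            class = "spectrum_psd")
}

#' @export
print.spectrum_psd <- function(x, ...) {
  cat(sprintf("spectrum_psd: %d bins, df = %g Hz, %d segment(s), total power %.3g\n",
              length(x$f), x$df, x$n_segments, sum(x$S) * x$df))
  invisible(x)
}

#' Average several spectra on a common grid
#'
#' Segment-count-weighted mean of `spectrum_psd` objects sharing one grid.
#'
#' @param spectra List of `spectrum_psd`.
#' @return A `spectrum_psd`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f <- spectra[[1]]$f
  for (sp in spectra)
    if (length(sp$f) != length(f) || max(abs(sp$f - f)) > 1e-9)
      stop("spectra are not on a common frequency grid", call. = FALSE)
  w <- vapply(spectra, `[[`, numeric(1), "n_segments")
  S <- Reduce(`+`, Map(function(sp, wi) sp$S * wi, spectra, w)) / sum(w)
  structure(list(f = f, S = S, df = spectra[[1]]$df,
                 n_segments = as.integer(sum(w))),
            class = "spectrum_psd")
}

#' Band-integrated spectral power
#'
#' Sum of PSD bins whose frequencies lie in the closed band, times the bin
#' width. The default band (0.025-4 Hz) is the sway-magnitude measure.
#'
#' @param spec A `spectrum_psd` from [segmented_psd()].
#' @param fmin,fmax Band edges (Hz), inclusive.
#' @return Scalar integrated power (unit^2).
#' @export
integrate_spectrum <- function(spec, fmin = 0.025, fmax = 4) {
  idx <- spec$f >= fmin - 1e-9 & spec$f <= fmax + 1e-9
  if (!any(idx)) stop("empty frequency band", call. = FALSE)
  sum(spec$S[idx]) * spec$df
}

#' Magnitude of the triaxial hand-force vector
#'
#' Elementwise Euclidean norm of the three force components plus its mean
#' over the analysis window, the trial-level interaction-force measure.
#'
#' @param Fx,Fy,Fz Force component series (N), equal lengths.
#' @param fs Sampling rate (Hz); needed only when `discard_s > 0`.
#' @param discard_s Leading time (s) excluded from the mean.
#' @return List with `magnitude` (N series) and `mean` (N scalar).
#' @export
force_magnitude <- function(Fx, Fy, Fz, fs = NULL, discard_s = 0) {
  stopifnot(length(Fx) == length(Fy), length(Fy) == length(Fz))
  mag <- sqrt(Fx^2 + Fy^2 + Fz^2)
  keep <- mag
  if (discard_s > 0) {
    stopifnot(!is.null(fs))
    keep <- mag[-seq_len(min(as.integer(round(discard_s * fs)), length(mag)))]
  }
  list(magnitude = mag, mean = mean(keep))
}

#' Unbiased normalised cross-correlation
#'
#' \deqn{R(\tau_k) = \frac{\sum_t x(t)\, y(t + \tau_k) / (N - |k|)}
#'   {\sigma_x \sigma_y}}
#' with both series demeaned and population standard deviations, evaluated
#' at lags `-maxlag..maxlag`. Positive lag means `x` precedes `y`. The
#' unbiased divisor makes `|R|` exceed 1 slightly at extreme lags possible;
#' `R(0)` of an autocorrelation is exactly 1. Computed via FFT in
#' O(N log N).
#'
#' @param x,y Equal-length series.
#' @param fs Sampling rate (Hz).
#' @param maxlag Maximum lag (s).
#' @return An `xcorr_result`: list with `lags` (s), `R`, `fs`.
#' @export
xcorr_unbiased <- function(x, y, fs, maxlag = 10) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  x <- x - mean(x)
  y <- y - mean(y)
  sx <- sqrt(mean(x^2))
  sy <- sqrt(mean(y^2))
  if (sx == 0 || sy == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  kmax <- min(as.integer(round(maxlag * fs)), n - 1L)
  # cross-correlation via zero-padded FFT: c[k] = sum_t x[t] y[t+k]
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  Y <- stats::fft(c(y, rep(0, nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  k <- -kmax:kmax
  raw <- cc[ifelse(k >= 0, k + 1, nfft + k + 1)]
  R <- raw / (n - abs(k)) / (sx * sy)
  structure(list(lags = k / fs, R = R, fs = fs), class = "xcorr_result")
}

#' Peak of a cross-correlation function
#'
#' The extremum of `|R|` within the computed lag range; the signed value
#' is reported (negative peaks are meaningful: reversed-feedback
#' conditions flip the force-position coupling). Ties in `|R|` resolve to
#' the smallest `|lag|`, then to the positive lag.
#'
#' @param r An `xcorr_result` from [xcorr_unbiased()].
#' @return List with `peak_R` (signed) and `peak_lag` (s).
#' @export
peak_xcorr <- function(r) {
  a <- abs(r$R)
  best <- which(a == max(a))
  if (length(best) > 1) {
    al <- abs(r$lags[best])
    best <- best[al == min(al)]
    if (length(best) > 1) best <- best[which.max(r$lags[best])]
  }
  list(peak_R = r$R[best], peak_lag = r$lags[best])
}
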