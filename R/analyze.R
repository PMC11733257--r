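#' Per-trial sway, force and coupling metrics
#'
#' Applies the empirical pipeline to one trial: integrated 0.025-4 Hz
#' power of trunk position and of velocity (zero-phase 5-Hz low-pass then
#' central difference), trial-mean triaxial force magnitude, and the peak
#' of the unbiased normalised cross-correlation between trunk position
#' and the AP force component. The first `discard_s` seconds are dropped
#' from every measure.
#'
#' @param record A [trial_record()].
#' @param discard_s Leading settling time (s) discarded.
#' @param maxlag Cross-correlation lag range (s).
#' @return One-row data frame: subject, condition, trial, `pos_power`
#'   (m^2), `vel_power` ((m/s)^2), `mean_force` (N), `peak_R`,
#'   `peak_lag` (s).
#' @export
trial_metrics <- function(record, discard_s = 10, maxlag = 10) {
  fs <- record$fs
  drop_n <- as.integer(round(discard_s * fs))
  keep <- seq.int(drop_n + 1L, length(record$t))
  x <- record$x_trunk[keep]
  v <- lowpass_then_differentiate(record$x_trunk, fs)[keep]
  pos_power <- integrate_spectrum(segmented_psd(x, fs))
  vel_power <- integrate_spectrum(segmented_psd(v, fs))
  fm <- force_magnitude(record$Fx[keep], record$Fy[keep], record$Fz[keep])
  pk <- peak_xcorr(xcorr_unbiased(x, record$Fx[keep], fs, maxlag = maxlag))
  data.frame(subject = record$subject, condition = record$condition,
             trial = record$trial, pos_power = pos_power,
             vel_power = vel_power, mean_force = fm$mean,
             peak_R = pk$peak_R, peak_lag = pk$peak_lag)
}

#' Analyse a full dataset through the empirical pipeline
#'
#' Per-trial metrics for every record, per-subject condition means, and
#' condition-mean position/velocity spectra (all trials of a condition
#' pooled segment-wise).
#'
#' @param records List of [trial_record()] (e.g. from
#'   [generate_dataset()] or [read_trial()]).
#' @param discard_s,maxlag See [trial_metrics()].
#' @return A `sway_analysis` list: `trials` (per-trial data frame),
#'   `subject_condition` (per-subject condition means, long format),
#'   `spectra` (per condition: `pos` and `vel` `spectrum_psd`),
#'   `conditions` (labels in design order).
#' @export
analyze_dataset <- function(records, discard_s = 10, maxlag = 10) {
  if (length(records) == 0) stop("no trial records given", call. = FALSE)
  trials <- do.call(rbind, lapply(records, trial_metrics,
                                  discard_s = discard_s, maxlag = maxlag))
  conditions <- unique(trials$condition)
  measures <- c("pos_power", "vel_power", "mean_force", "peak_R", "peak_lag")
  sc <- do.call(rbind, lapply(measures, function(msr) {
    agg <- stats::aggregate(trials[[msr]],
                            list(subject = trials$subject,
                                 condition = trials$condition), mean)
    data.frame(measure = msr, agg[, c("subject", "condition")],
               value = agg$x)
  }))
  spectra <- lapply(conditions, function(cond) {
    recs <- records[vapply(records, function(r)
      identical(r$condition, cond), logical(1))]
    fs <- recs[[1]]$fs
    drop_n <- as.integer(round(discard_s * fs))
    pos <- segmented_psd(lapply(recs, function(r)
      r$x_trunk[-seq_len(drop_n)]), fs)
    vel <- segmented_psd(lapply(recs, function(r)
      lowpass_then_differentiate(r$x_trunk, fs)[-seq_len(drop_n)]), fs)
    list(pos = pos, vel = vel)
  })
  names(spectra) <- conditions
  structure(list(trials = trials, subject_condition = sc,
                 spectra = spectra, conditions = conditions),
            class = "sway_analysis")
}

#' @export
print.sway_analysis <- function(x, ...) {
  cat(sprintf("sway_analysis: %d trials, %d subjects, %d conditions\n",
              nrow(x$trials), length(unique(x$trials$subject)),
              length(x$conditions)))
  invisible(x)
}

#' Condition-level repeated-measures inference for one measure
#'
#' Builds the subject-by-condition table for `measure` and runs the
#' omnibus repeated-measures ANOVA plus Tukey-corrected pairwise
#' comparisons. Force and coupling measures are conventionally tested on
#' the touch conditions only (`conditions` restricts the table).
#'
#' @param analysis A `sway_analysis` from [analyze_dataset()].
#' @param measure One of `"pos_power"`, `"vel_power"`, `"mean_force"`,
#'   `"peak_R"`, `"peak_lag"`.
#' @param conditions Optional subset/ordering of condition labels.
#' @return List with `table` ([condition_table()]), `anova`
#'   ([rm_anova()]) and `pairwise` ([tukey_pairwise()]).
#' @export
condition_anova <- function(analysis, measure = "pos_power",
                            conditions = NULL) {
  sc <- analysis$subject_condition
  sc <- sc[sc$measure == measure, ]
  if (is.null(conditions)) conditions <- analysis$conditions
  sc <- sc[sc$condition %in% conditions, ]
  tab <- tapply(sc$value, list(sc$subject, sc$condition), mean)
  tab <- tab[, conditions, drop = FALSE]
  tab <- condition_table(tab)
  a <- rm_anova(tab)
  list(table = tab, anova = a, pairwise = tukey_pairwise(tab, a))
}
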