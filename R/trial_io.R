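#' One experimental (or synthetic) trial record
#'
#' Container for a single standing trial: time, anterior-posterior trunk
#' and robot position (m) and the triaxial hand force (N) at a uniform
#' sampling rate, plus identifying metadata.
#'
#' @param t,x_trunk,x_robot,Fx,Fy,Fz Equal-length series (SI units).
#' @param fs Sampling rate (Hz).
#' @param subject,condition,trial Metadata: subject id, condition label
#'   (a gain label such as `"-0.5"`, or `"notouch"`), trial index.
#' @return A `trial_record`.
#' @export
trial_record <- function(t, x_trunk, x_robot, Fx, Fy, Fz, fs,
                         subject, condition, trial) {
  n <- length(t)
  stopifnot(length(x_trunk) == n, length(x_robot) == n,
            length(Fx) == n, length(Fy) == n, length(Fz) == n, fs > 0)
  structure(list(t = as.numeric(t), x_trunk = as.numeric(x_trunk),
                 x_robot = as.numeric(x_robot), Fx = as.numeric(Fx),
                 Fy = as.numeric(Fy), Fz = as.numeric(Fz),
                 fs = as.numeric(fs),
                 subject = as.character(subject),
                 condition = as.character(condition),
                 trial = as.integer(trial)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial_record %s/%s #%d: %.1f s at %g Hz\n",
              x$subject, x$condition, x$trial, length(x$t) / x$fs, x$fs))
  invisible(x)
}

TRIAL_SCHEMA_VERSION <- "1"
TRIAL_COLUMNS <- c("t", "x_trunk", "x_robot", "Fx", "Fy", "Fz")

#' Write a trial record to its CSV dialect
#'
#' Plain CSV with a commented header carrying the schema version, subject,
#' condition, trial index and sampling rate, followed by the six data
#' columns in SI units. Round-trips losslessly through [read_trial()].
#'
#' @param record A [trial_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(record, path) {
  stopifnot(inherits(record, "trial_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# haptic-trial v%s", TRIAL_SCHEMA_VERSION),
               sprintf("# subject: %s", record$subject),
               sprintf("# condition: %s", record$condition),
               sprintf("# trial: %d", record$trial),
               sprintf("# fs: %.10g", record$fs)), con)
  df <- as.data.frame(record[TRIAL_COLUMNS])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial record from its CSV dialect
#'
#' Validates the schema version, the presence of every column, and that
#' the declared sampling rate matches the row spacing to within 1 ns.
#'
#' @param path File written by [write_trial()].
#' @return A [trial_record()].
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 5)
  if (!grepl("^# haptic-trial v", hdr[1]))
    stop("not a haptic-trial file: ", path, call. = FALSE)
  ver <- sub("^# haptic-trial v", "", hdr[1])
  if (ver != TRIAL_SCHEMA_VERSION)
    stop("unsupported schema version ", ver, call. = FALSE)
  meta <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ": "), hdr)]
    if (length(ln) != 1) stop("missing header field ", key, call. = FALSE)
    sub(paste0("^# ", key, ": "), "", ln)
  }
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  fs <- as.numeric(meta("fs"))
  if (nrow(df) > 1) {
    dtv <- diff(df$t)
    if (max(abs(dtv - 1 / fs)) > 1e-9)
      stop("integrity error: declared fs = ", fs,
           " Hz does not match row spacing", call. = FALSE)
  }
  trial_record(df$t, df$x_trunk, df$x_robot, df$Fx, df$Fy, df$Fz,
               fs = fs, subject = meta("subject"),
               condition = meta("condition"),
               trial = as.integer(meta("trial")))
}

#' Write a dataset manifest
#'
#' JSON snapshot of the design, model parameters and seeds attached by
#' [generate_dataset()]; regenerating from the manifest reproduces the
#' dataset byte-identically.
#'
#' @param records Dataset from [generate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  manifest <- attr(records, "manifest")
  if (is.null(manifest)) stop("records carry no manifest", call. = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Regenerate a dataset from its manifest
#'
#' @param path Manifest JSON written by [write_manifest()].
#' @return The regenerated dataset (list of `trial_record`).
#' @export
regenerate_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(experiment_design, c(
    m$design[c("n_subjects", "trials_per_condition", "trial_s", "fs",
               "discard_s", "device_lag", "master_seed")],
    list(gains = m$design$gains,
         include_no_touch = "notouch" %in% m$design$conditions)))
  body <- do.call(body_params, m$model$body)
  ctrl <- control_params(body, Kp = m$model$ctrl$Kp, Kd = m$model$ctrl$Kd,
                         delay = m$model$ctrl$delay,
                         w_touch = m$model$ctrl$w_touch)
  cp <- conflict_params(Te = m$model$conflict$Te,
                        mode = m$model$conflict$mode,
                        leak_tau = if (is.null(m$model$conflict$leak_tau) ||
                                       !is.numeric(m$model$conflict$leak_tau))
                          Inf else m$model$conflict$leak_tau)
  np <- do.call(noise_params, m$model$noise)
  force <- do.call(force_coupling_params, m$force)
  generate_dataset(design, body, ctrl, cp, np, force,
                   body_jitter_sd = m$jitter$body_sd,
                   knoise_jitter_sd = m$jitter$k_noise_sd)
}
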