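#' Build a subject-by-condition table of per-subject means
#'
#' @param values Numeric matrix, subjects in rows, conditions in columns,
#'   or a data frame with columns `subject`, `condition`, `value` which is
#'   averaged into that matrix.
#' @return A `condition_table`: the complete matrix with condition labels.
#' @export
condition_table <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("subject", "condition", "value") %in% names(values)))
    values <- tapply(values$value, list(values$subject, values$condition),
                     mean)
  }
  values <- as.matrix(values)
  if (anyNA(values)) stop("condition table has missing cells", call. = FALSE)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  structure(values, class = c("condition_table", "matrix"))
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way design: each of n subjects contributes
#' one mean per condition; `F = MS_condition / MS_error` after removing
#' subject means, on `(k-1, (k-1)(n-1))` degrees of freedom (reported
#' uncorrected, as is conventional for these designs). A
#' Greenhouse-Geisser-corrected p is attached as a labelled extra.
#' Fitted via `stats::aov` with an `Error(subject)` stratum.
#'
#' @param tab A [condition_table()] (or matrix/data frame accepted by it).
#' @return An `anova_rm` list: `F`, `df1`, `df2`, `p`, `MS_error`,
#'   `means` (condition means), `n` (subjects), `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(tab) {
  tab <- condition_table(unclass(tab))
  n <- nrow(tab); k <- ncol(tab)
  long <- data.frame(
    value = as.vector(tab),
    subject = factor(rep(rownames(tab), times = k)),
    condition = factor(rep(colnames(tab), each = n),
                       levels = colnames(tab)))
  fit <- stats::aov(value ~ condition + Error(subject), data = long)
  s <- summary(fit)[["Error: Within"]][[1]]
  Fval <- s["condition", "F value"]
  df1 <- s["condition", "Df"]
  df2 <- s["Residuals", "Df"]
  MSe <- s["Residuals", "Mean Sq"]
  # degenerate table (condition means numerically equal): the QR residue
  # makes the 0/0 ratio meaningless, report F = 0
  scale <- stats::sd(as.vector(tab))
  if (!is.finite(Fval) ||
      (scale > 0 && diff(range(colMeans(tab))) < 1e-10 * scale) ||
      scale == 0)
    Fval <- 0
  p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  eps <- gg_epsilon(tab)
  structure(list(F = Fval, df1 = df1, df2 = df2, p = p,
                 MS_error = MSe, means = colMeans(tab), n = n,
                 gg_epsilon = eps,
                 p_gg = stats::pf(Fval, df1 * eps, df2 * eps,
                                  lower.tail = FALSE)),
            class = "anova_rm")
}

# Greenhouse-Geisser sphericity estimate from the double-centred
# condition covariance matrix.
gg_epsilon <- function(tab) {
  S <- stats::cov(unclass(tab))
  k <- ncol(S)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  min(1, sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2)))
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d,%d) = %.3g, p = %.3g (GG eps = %.3f, p_GG = %.3g)\n",
              x$df1, x$df2, x$F, x$p, x$gg_epsilon, x$p_gg))
  invisible(x)
}

#' Tukey-corrected pairwise comparisons for a within-subject design
#'
#' Studentized-range test on every condition pair using the ANOVA error
#' mean square: `q = |mean_i - mean_j| / sqrt(MS_error / n)`, with the
#' adjusted p from the studentized-range distribution on `(k, df2)`.
#' Always computed; whether to report only after a significant omnibus F
#' is the caller's policy.
#'
#' @param tab A [condition_table()].
#' @param anova Optional `anova_rm` result for `tab` (recomputed if
#'   missing).
#' @return Data frame with columns `a`, `b`, `diff`, `q`, `p_adj`.
#' @export
tukey_pairwise <- function(tab, anova = rm_anova(tab)) {
  tab <- condition_table(unclass(tab))
  k <- ncol(tab)
  se <- sqrt(anova$MS_error / anova$n)
  pairs <- utils::combn(colnames(tab), 2)
  d <- anova$means[pairs[1, ]] - anova$means[pairs[2, ]]
  q <- abs(d) / se
  data.frame(a = pairs[1, ], b = pairs[2, ], diff = as.numeric(d),
             q = as.numeric(q),
             p_adj = stats::ptukey(q, nmeans = k, df = anova$df2,
                                   lower.tail = FALSE),
             row.names = NULL)
}
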