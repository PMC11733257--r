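#!/usr/bin/env Rscript
# Stage 4 — condition-level inference on the synthetic experiment.
#
# One-way repeated-measures ANOVA per measure (uncorrected F and df, as
# conventional, with a Greenhouse-Geisser p as a labelled extra) followed
# by Tukey-corrected pairwise comparisons. Sway-power measures are tested
# over all ten conditions; force and coupling measures over the nine
# touch conditions, as the no-touch force channel carries no contact.
# Requires stage 3's subject_condition_means.csv.

suppressPackageStartupMessages(library(hapticsway))
sc <- read.csv("results/subject_condition_means.csv",
               colClasses = c(condition = "character"))
gl <- format_gain(study_gains())

an <- list(subject_condition = sc,
           conditions = c(gl, "notouch"))

specs <- list(pos_power = an$conditions, vel_power = an$conditions,
              mean_force = gl, peak_R = gl, peak_lag = gl)
omnibus <- list(); pairwise <- list()
for (msr in names(specs)) {
  ca <- condition_anova(an, msr, conditions = specs[[msr]])
  a <- ca$anova
  omnibus[[msr]] <- data.frame(measure = msr, F = a$F, df1 = a$df1,
                               df2 = a$df2, p = a$p,
                               gg_epsilon = a$gg_epsilon, p_gg = a$p_gg)
  pairwise[[msr]] <- data.frame(measure = msr, ca$pairwise)
  message(sprintf("%-10s F(%d,%d) = %6.2f, p = %.2g", msr, a$df1, a$df2,
                  a$F, a$p))
}
write.csv(do.call(rbind, omnibus), "results/anova_omnibus.csv",
          row.names = FALSE)
write.csv(do.call(rbind, pairwise), "results/anova_pairwise.csv",
          row.names = FALSE)
message("Wrote results/anova_omnibus.csv, results/anova_pairwise.csv")
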