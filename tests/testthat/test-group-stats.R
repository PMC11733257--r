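test_that("identical condition columns give F = 0", {
  base <- rnorm(6, sd = 2)
  tab <- matrix(rep(base, 4), nrow = 6,
                dimnames = list(NULL, paste0("g", 1:4)))
  a <- rm_anova(tab)
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-12)
})

test_that("study-sized table reports the conventional degrees of freedom", {
  set.seed(10)
  tab <- matrix(rnorm(14 * 10), 14, 10)
  a <- rm_anova(tab)
  expect_equal(a$df1, 9)
  expect_equal(a$df2, 117)
})

test_that("F statistic matches an explicit sum-of-squares oracle", {
  set.seed(11)
  tab <- matrix(rnorm(12, mean = rep(c(0, 1, 3, 3), each = 3)), 3, 4)
  a <- rm_anova(tab)
  o <- rm_anova_oracle(tab)
  expect_equal(a$F, o$F, tolerance = 1e-10)
  expect_equal(a$df1, o$df1)
  expect_equal(a$df2, o$df2)
  expect_equal(a$MS_error, o$MS_error, tolerance = 1e-10)
})

test_that("F is invariant to adding per-subject constants", {
  set.seed(12)
  tab <- matrix(rnorm(40), 8, 5)
  shifted <- tab + rnorm(8, sd = 10)  # recycled down columns: per-subject
  expect_equal(rm_anova(tab)$F, rm_anova(shifted)$F, tolerance = 1e-10)
})

test_that("rm_anova accepts long data frames and enforces completeness", {
  set.seed(13)
  long <- expand.grid(subject = paste0("S", 1:4), condition = c("a", "b", "c"))
  long$value <- rnorm(nrow(long))
  tab <- condition_table(long)
  expect_equal(dim(tab), c(4L, 3L))
  a <- rm_anova(tab)
  expect_equal(a$df2, 6)
  bad <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(condition_table(bad), "missing")
  expect_error(condition_table(matrix(1:3, 3, 1)), "at least 2")
})

test_that("Tukey q statistics match the direct studentized-range formula", {
  set.seed(14)
  tab <- matrix(rnorm(18, mean = rep(c(0, 0.5, 2), each = 6)), 6, 3,
                dimnames = list(NULL, c("lo", "mid", "hi")))
  a <- rm_anova(tab)
  pw <- tukey_pairwise(tab, a)
  o <- rm_anova_oracle(tab)
  means <- colMeans(tab)
  for (i in seq_len(nrow(pw))) {
    q_direct <- abs(means[pw$a[i]] - means[pw$b[i]]) /
      sqrt(o$MS_error / nrow(tab))
    expect_equal(pw$q[i], as.numeric(q_direct), tolerance = 1e-10)
    expect_equal(pw$p_adj[i],
                 as.numeric(stats::ptukey(q_direct, 3, o$df2,
                                          lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
})

test_that("equal condition means give an adjusted p of 1", {
  set.seed(15)
  subj <- rnorm(10)
  tab <- cbind(a = subj + rnorm(10, sd = 0.1),
               b = subj + rnorm(10, sd = 0.1))
  tab[, 2] <- tab[, 2] - mean(tab[, 2]) + mean(tab[, 1])
  pw <- tukey_pairwise(tab)
  expect_equal(pw$p_adj, 1, tolerance = 1e-6)
})

test_that("larger mean separation never raises the adjusted p", {
  set.seed(16)
  tab <- matrix(rnorm(32, mean = rep(c(0, 1, 2, 5), each = 8)), 8, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
  pw <- tukey_pairwise(tab)
  ord <- order(abs(pw$diff))
  expect_true(all(diff(pw$p_adj[ord]) <= 1e-12))
})

test_that("adjusted p values are invariant to condition relabeling", {
  set.seed(17)
  tab <- matrix(rnorm(24, mean = rep(c(0, 1, 3), each = 8)), 8, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  pw1 <- tukey_pairwise(tab)
  perm <- tab[, c(3, 1, 2)]
  pw2 <- tukey_pairwise(perm)
  expect_equal(sort(pw1$p_adj), sort(pw2$p_adj), tolerance = 1e-12)
  expect_equal(rm_anova(tab)$F, rm_anova(perm)$F, tolerance = 1e-12)
})

test_that("Greenhouse-Geisser epsilon lies in its admissible range", {
  set.seed(18)
  tab <- matrix(rnorm(14 * 10), 14, 10)
  a <- rm_anova(tab)
  expect_gte(a$gg_epsilon, 1 / 9)
  expect_lte(a$gg_epsilon, 1 + 1e-12)
  # under strong compound symmetry violation epsilon shrinks the dfs
  tab2 <- tab %*% diag(c(10, rep(0.1, 9)))
  expect_lt(rm_anova(tab2)$gg_epsilon, 0.5)
})
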