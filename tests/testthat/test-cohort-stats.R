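test_that("Grubbs screen matches hand evaluation and the t-quantile oracle", {
  ## symmetric small set: no outlier
  expect_length(grubbs_screen(c(1, 2, 3))$outlier_idx, 0)

  ## {1,1,1,10}: G = 1.5, critical ~ 1.481 at alpha 0.05
  res <- grubbs_screen(c(1, 1, 1, 10), alpha = 0.05)
  expect_equal(res$g[1], (10 - 3.25) / sd(c(1, 1, 1, 10)))
  expect_equal(res$g[1], 1.5, tolerance = 1e-12)
  t_or <- qt(1 - 0.05 / 8, 2)
  expect_equal(res$critical[1], 3 / 2 * sqrt(t_or^2 / (2 + t_or^2)))
  expect_equal(res$critical[1], 1.481, tolerance = 1e-3)
  expect_identical(res$outlier_idx, 4L)

  ## alpha -> 0 flags nothing
  expect_length(grubbs_screen(c(1, 1, 1, 10), alpha = 1e-12)$outlier_idx, 0)

  ## constant data: zero sd, no outlier
  expect_length(grubbs_screen(rep(2, 5))$outlier_idx, 0)
  expect_error(grubbs_screen(c(1, 2)), "insufficient data")
})

test_that("Grubbs flags are invariant under affine transforms", {
  set.seed(20)
  x <- c(rnorm(10), 8)
  base <- grubbs_screen(x)$outlier_idx
  expect_identical(grubbs_screen(3 * x - 7)$outlier_idx, base)
  expect_identical(grubbs_screen(-0.5 * x + 100)$outlier_idx, base)
})

test_that("cell-wise table screening removes planted outliers", {
  tc <- trajectory_config(missingness = 0, outlier_rate = 0.02)
  co <- generate_cohort(tc, n_per_cell = 10, seed = 6)
  beh <- co$behaviour
  screened <- grubbs_screen_table(beh)
  planted <- which(beh$outlier)
  ## the single-pass screen has real power against +/-4 SD shifts: recall
  ## far above the false-flag rate (a 4 SD value inflates the cell SD, so
  ## per-cell recall at n = 10 sits near 40%, not 100%)
  recall <- mean(screened$screened[planted])
  fp <- mean(screened$screened[-planted])
  expect_gt(recall, 0.25)
  expect_lt(fp, 0.01)
  expect_gt(recall, 20 * fp)
})

test_that("factorial ANOVA matches the closed-form balanced decomposition", {
  ## balanced 2x2 with hand-computable cell means
  d <- expand.grid(g = c("a", "b"), s = c("m", "f"), rep = 1:5)
  mu <- c(a.m = 10, b.m = 12, a.f = 11, b.f = 17)
  set.seed(2)
  d$y <- mu[paste(d$g, d$s, sep = ".")] + rnorm(nrow(d), 0, 1)

  res <- factorial_anova(d, c("g", "s"), "y")

  ## closed-form two-way decomposition for a balanced design
  n <- 5
  cm <- tapply(d$y, list(d$g, d$s), mean)
  gm <- mean(d$y)
  ss_a <- 2 * n * sum((rowMeans(cm) - gm)^2)
  ss_b <- 2 * n * sum((colMeans(cm) - gm)^2)
  ss_ab <- n * sum((cm - outer(rowMeans(cm), colMeans(cm), `+`) + gm)^2)
  ss_e <- sum((d$y - cm[cbind(d$g, d$s)])^2)
  f_hand <- c(ss_a, ss_b, ss_ab) / (ss_e / (nrow(d) - 4))
  expect_equal(res$F, f_hand, tolerance = 1e-10)

  ## on balanced data Type III equals the sequential decomposition
  seq_aov <- anova(lm(y ~ g * s, data = d))
  expect_equal(res$F, seq_aov$`F value`[1:3], tolerance = 1e-10)
})

test_that("constant responses yield zero F throughout", {
  d <- expand.grid(g = c("a", "b"), s = c("m", "f"), rep = 1:3)
  d$y <- 7
  res <- factorial_anova(d, c("g", "s"), "y")
  expect_true(all(res$F == 0))
})

test_that("three-way ANOVA detects a planted genotype effect", {
  co <- generate_cohort(clean_trajectory(), n_per_cell = 8, seed = 9)
  beh <- co$behaviour[co$behaviour$measure == "locomotor_activity", ]
  res <- factorial_anova(beh, c("genotype", "sex", "age_weeks"))
  f_gen <- res$F[res$term == "genotype"]
  expect_gt(f_gen, 10)
  expect_lt(res$p[res$term == "genotype"], 0.001)

  ## null configuration: genotype p roughly uniform across seeds
  ps <- vapply(1:12, function(s) {
    co0 <- generate_cohort(null_trajectory_config(missingness = 0,
                                                  outlier_rate = 0),
                           n_per_cell = 5,
                           behaviour_ages = c(9, 94), seed = s)
    b0 <- co0$behaviour[co0$behaviour$measure == "grip_fore", ]
    r0 <- factorial_anova(b0, c("genotype", "sex"))
    r0$p[r0$term == "genotype"]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.6)

  ## degenerate design errors name the factor
  bad <- beh[beh$sex == "male", ]
  expect_error(factorial_anova(bad, c("genotype", "sex")),
               "design degeneracy.*sex")
})

test_that("Bonferroni-adjusted alpha follows the comparison count", {
  set.seed(30)
  mk <- function(k, n = 25) {
    as.data.frame(matrix(rnorm(n * k), n, k,
                         dimnames = list(NULL, paste0("m", seq_len(k)))))
  }
  r6 <- bonferroni_correlations(mk(6))
  expect_equal(r6$n_comparisons, 15)
  expect_equal(round(r6$adjusted_alpha, 4), 0.0033)

  r7 <- bonferroni_correlations(mk(7))
  expect_equal(r7$n_comparisons, 21)
  expect_equal(round(r7$adjusted_alpha, 4), 0.0024)

  r2 <- bonferroni_correlations(mk(2))
  expect_equal(r2$n_comparisons, 1)
  expect_equal(r2$adjusted_alpha, 0.05)
})

test_that("correlation matrices are symmetric, unit-diagonal and PSD", {
  set.seed(31)
  n <- 40
  base <- rnorm(n)
  d <- data.frame(a = base + rnorm(n, 0, 0.5), b = base + rnorm(n, 0, 0.5),
                  c = rnorm(n), e = rnorm(n))
  res <- bonferroni_correlations(d)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(eigen(res$r, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  ## the correlated pair is flagged at the corrected level
  expect_true(res$significant["a", "b"])
  expect_false(res$significant["c", "e"])
})

test_that("long-format tables reshape into the correlation layout", {
  set.seed(32)
  long <- expand.grid(subject = paste0("s", 1:20),
                      measure = c("x", "y", "z"), stringsAsFactors = FALSE)
  long$value <- rnorm(nrow(long))
  res <- bonferroni_correlations(long)
  expect_equal(dim(res$r), c(3, 3))
  expect_equal(res$n_comparisons, 3)
})

test_that("post-hoc Bonferroni comparisons scale raw p by the pair count", {
  set.seed(33)
  v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 3))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  res <- posthoc_bonferroni(v, g)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))

  ## identical groups: adjusted p saturates near 1
  same <- posthoc_bonferroni(rep(c(1.0, 1.1, 0.9, 1.05), 2),
                             rep(c("a", "b"), each = 4))
  expect_gt(same$p_adjusted, 0.5)
  expect_error(posthoc_bonferroni(v, rep("only", 30)), "fewer than 2")
})

test_that("only truly different pairs are flagged across seeded repeats", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    v <- c(rnorm(8, 0, 1), rnorm(8, 0, 1), rnorm(8, 2.5, 1))
    g <- rep(c("a", "b", "c"), each = 8)
    res <- posthoc_bonferroni(v, g)
    sig <- res[res$p_adjusted < 0.05, ]
    true_pair <- all(grepl("c", paste(sig$group1, sig$group2)))
    found <- any(grepl("c", paste(sig$group1, sig$group2)))
    true_pair && found
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
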