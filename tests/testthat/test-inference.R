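test_that("one-way RM-ANOVA matches the definitional sums of squares", {
  # worked example: S = 2 subjects, 3 conditions
  y <- matrix(c(1, 2, 2, 3, 3, 5), 2, 3)
  res <- rm_anova_oneway(y)
  expect_equal(res$f_value, 19)
  expect_equal(c(res$df_num, res$df_den), c(2L, 2L))
  # brute-force agreement on random tables
  set.seed(21)
  for (i in 1:100) {
    S <- sample(3:8, 1); N <- sample(3:7, 1)
    y <- matrix(rnorm(S * N), S, N)
    res <- rm_anova_oneway(y)
    bf <- oneway_anova_bruteforce(y)
    expect_equal(res$f_value, bf$f, tolerance = 1e-9)
    expect_equal(res$p_value, bf$p, tolerance = 1e-9)
    expect_equal(res$ss_effect, bf$ss_cond, tolerance = 1e-9)
    expect_equal(res$ss_error, bf$ss_err, tolerance = 1e-9)
  }
})

test_that("one-way RM-ANOVA degrees of freedom follow (N-1, (N-1)(S-1))", {
  set.seed(22)
  res5 <- rm_anova_oneway(matrix(rnorm(16 * 5), 16, 5))
  expect_equal(c(res5$df_num, res5$df_den), c(4L, 60L))
  res12 <- rm_anova_oneway(matrix(rnorm(16 * 12), 16, 12))
  expect_equal(c(res12$df_num, res12$df_den), c(11L, 165L))
})

test_that("pure subject effects produce F = 0; zero error SS flags F = Inf", {
  # identical condition profile shifted per subject: no condition effect
  y <- outer(c(0, 1, 5), rep(1, 4)) + matrix(rep(0, 12), 3, 4)
  res <- rm_anova_oneway(y)
  expect_equal(res$ss_effect, 0)
  expect_equal(res$f_value, 0)
  # exact additive subject + condition structure: zero error SS
  y2 <- outer(c(0, 1, 2), c(0, 3, 5, 9), `+`)
  res2 <- rm_anova_oneway(y2)
  expect_true(res2$degenerate)
  expect_equal(res2$f_value, Inf)
  expect_equal(res2$p_value, 0)
})

test_that("F statistics are invariant to per-subject constants", {
  set.seed(23)
  y <- matrix(rnorm(6 * 6), 6, 6)
  shift <- y + matrix(rnorm(6), 6, 6)[, rep(1, 6)]  # constant per row
  expect_equal(rm_anova_oneway(shift)$f_value, rm_anova_oneway(y)$f_value,
               tolerance = 1e-9)
  des <- design_2x3()
  f0 <- rm_anova_factorial(y, des)$f_value
  f1 <- rm_anova_factorial(shift, des)$f_value
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("factorial RM-ANOVA matches aov with within-subject error strata", {
  set.seed(24)
  S <- 10
  des <- design_2x2x3()
  y <- matrix(rnorm(S * 12), S, 12,
              dimnames = list(NULL, des$condition_labels))
  ours <- as.data.frame(rm_anova_factorial(y, des))
  df <- data.frame(
    y = as.vector(y), subj = factor(rep(seq_len(S), 12)),
    phase = factor(rep(des$factor_levels$phase, each = S)),
    dir = factor(rep(des$factor_levels$dir, each = S)),
    load = factor(rep(des$factor_levels$load, each = S)))
  ref <- summary(stats::aov(
    y ~ phase * dir * load + Error(subj / (phase * dir * load)), data = df))
  for (stratum in ref) {
    tab <- stratum[[1]]
    for (rn in rownames(tab)) {
      eff <- trimws(rn)
      if (eff == "Residuals") next
      i <- match(eff, ours$effect)
      expect_false(is.na(i), info = eff)
      expect_equal(ours$f_value[i], tab[rn, "F value"], tolerance = 1e-9)
      expect_equal(ours$p_value[i], tab[rn, "Pr(>F)"], tolerance = 1e-9)
    }
  }
  # df bookkeeping: 2x2x3 crossing
  expect_equal(sum(ours$df_num), 11)
  expect_equal(ours$df_num[ours$effect == "phase:load"], 2)
  expect_equal(ours$df_den[ours$effect == "phase:load"], 2 * (S - 1))
})

test_that("factorial df match the working-memory design at S = 16", {
  set.seed(25)
  des <- design_2x2x3()
  y <- matrix(rnorm(16 * 12), 16, 12)
  res <- as.data.frame(rm_anova_factorial(y, des))
  expect_equal(
    unlist(res[res$effect == "phase:load", c("df_num", "df_den")]),
    c(df_num = 2, df_den = 30))
  expect_equal(
    unlist(res[res$effect == "dir", c("df_num", "df_den")]),
    c(df_num = 1, df_den = 15))
})

test_that("one-factor factorial reduces to the one-way ANOVA", {
  set.seed(26)
  y <- matrix(rnorm(7 * 5), 7, 5)
  des <- condition_design(sprintf("c%d", 1:5))
  fact <- as.data.frame(rm_anova_factorial(y, des))
  one <- rm_anova_oneway(y)
  expect_equal(fact$f_value, one$f_value)
  expect_equal(fact$df_num, one$df_num)
  expect_equal(fact$df_den, one$df_den)
  expect_equal(fact$p_value, one$p_value)
})

test_that("factorial SS partition conserves the total SS", {
  set.seed(27)
  des <- design_2x2x3()
  y <- matrix(rnorm(9 * 12), 9, 12)
  res <- rm_anova_factorial(y, des)
  part <- attr(res, "partition")
  acc <- part[["ss_subject"]] + sum(res$ss_effect) + sum(res$ss_error)
  expect_equal(acc, part[["ss_total"]], tolerance = 1e-9)
  expect_error(
    rm_anova_factorial(y[, 1:11],
                       condition_design(des$condition_labels[1:11],
                                        des$factor_levels[1:11, ])),
    "complete")
})

test_that("paired t-test matches its closed form and handles degeneracy", {
  # d = (1,2,3): t = 2*sqrt(3), one-sided p from the df=2 closed form
  res <- paired_ttest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t_value, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  t0 <- 2 * sqrt(3)
  expect_equal(res$p_value, 1 - 0.5 * (1 + t0 / sqrt(2 + t0^2)),
               tolerance = 1e-12)
  # a = b -> t = 0, two-sided p = 1
  resi <- paired_ttest(c(1, 2), c(1, 2), tail = "two.sided")
  expect_equal(resi$t_value, 0)
  expect_equal(resi$p_value, 1)
  # df = S - 1
  set.seed(28)
  res16 <- paired_ttest(rnorm(16), rnorm(16))
  expect_equal(res16$df, 15L)
  # constant nonzero difference: infinite t, flagged
  resc <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(resc$degenerate)
  expect_equal(resc$t_value, Inf)
  expect_equal(resc$p_value, 0)
  # one-sided p is half the two-sided p for t > 0
  a <- rnorm(10) + 0.5; b <- rnorm(10)
  r1 <- paired_ttest(a, b, "greater")
  r2 <- paired_ttest(a, b, "two.sided")
  if (r1$t_value > 0) expect_equal(r1$p_value, r2$p_value / 2)
})

test_that("null simulation keeps type-I rates near nominal for all tests", {
  set.seed(29)
  S <- 8; n_reps <- 2000
  des <- design_2x3()
  p_one <- p_fact <- p_t <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    y <- matrix(rnorm(S * 6), S, 6)
    p_one[r] <- rm_anova_oneway(y)$p_value
    fact <- rm_anova_factorial(y, des)
    p_fact[r] <- fact$p_value[fact$effect == "phase:load"]
    p_t[r] <- paired_ttest(y[, 1], y[, 2], "two.sided")$p_value
  }
  expect_gte(mean(p_one < 0.05), 0.03); expect_lte(mean(p_one < 0.05), 0.07)
  expect_gte(mean(p_fact < 0.05), 0.03); expect_lte(mean(p_fact < 0.05), 0.07)
  expect_gte(mean(p_t < 0.05), 0.03); expect_lte(mean(p_t < 0.05), 0.07)
})
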