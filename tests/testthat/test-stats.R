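# Group-comparison battery.

test_that("unpaired t handles identity, separation and effect size", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$cohens_d, 0)
  # near-degenerate separation drives p toward 0
  sep <- unpaired_t(c(1, 2, 3) / 1e6, 10 + c(1, 2, 3) / 1e6)
  expect_lt(sep$p, 1e-12)
  # Cohen's d against the direct formula oracle
  set.seed(51)
  a <- rnorm(15, 1); b <- rnorm(14)
  r <- unpaired_t(a, b)
  sp <- sqrt(((14) * var(a) + (13) * var(b)) / 27)
  expect_equal(r$cohens_d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(r$df, 27)
  # degenerate equal constants
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$p, 1)
})

test_that("Welch fallback engages only when variances differ", {
  set.seed(52)
  a <- rnorm(30); b <- rnorm(30, 0, 5)
  r <- unpaired_t(a, b, welch_fallback = TRUE)
  expect_true(r$variance_flag)
  expect_equal(r$method, "welch")
  r2 <- unpaired_t(a, b, welch_fallback = FALSE)
  expect_equal(r2$method, "pooled")
})

test_that("two-way ANOVA matches the closed-form balanced oracle", {
  const <- two_way_anova(rep(5, 12), rep(c("a", "b"), 6),
                         rep(c("x", "y"), each = 6))
  expect_equal(const$anova$f[1:3], c(0, 0, 0))
  # balanced 2x2 with a pure A effect
  set.seed(53)
  A <- rep(c("wt", "mut"), each = 20)
  B <- rep(rep(c("L", "D"), each = 10), 2)
  y <- rnorm(40, sd = 0.5) + (A == "mut") * 2
  fit <- two_way_anova(y, A, B)
  # closed-form balanced SS oracle
  g <- mean(y)
  ssA <- 20 * sum((tapply(y, A, mean) - g)^2)
  ssB <- 20 * sum((tapply(y, B, mean) - g)^2)
  cellm <- tapply(y, list(A, B), mean)
  ssAB <- 10 * sum((sweep(sweep(cellm, 1, tapply(y, A, mean)), 2,
                          tapply(y, B, mean)) + g)^2)
  sse <- sum((y - ave(y, A, B))^2)
  an <- fit$anova
  expect_equal(an$ss[an$effect == "A"], ssA, tolerance = 1e-8)
  expect_equal(an$ss[an$effect == "B"], ssB, tolerance = 1e-8)
  expect_equal(an$ss[an$effect == "A:B"], ssAB, tolerance = 1e-8)
  expect_equal(an$ss[an$effect == "error"], sse, tolerance = 1e-8)
  # decomposition: SS_A + SS_B + SS_AB + SS_error = SS_total (balanced)
  expect_equal(sum(an$ss), sum((y - g)^2), tolerance = 1e-8)
  expect_lt(an$p[an$effect == "A"], an$p[an$effect == "B"])
  expect_error(two_way_anova(1:3, c("a", "a", "b"), c("x", "y", "y")),
               "empty design cell")
})

test_that("the preset genotype-by-phase interaction is detectable", {
  # REM minutes per phase, 12 subjects per genotype, 2 days each
  pre <- genotype_presets()
  hits <- 0
  nseed <- 10
  for (s in seq_len(nseed)) {
    vals <- NULL; gt <- NULL; ph <- NULL
    for (g in c("WT", "MUT")) for (i in 1:12) {
      hyp <- simulate_hypnogram(pre[[g]]$kinetics, days = 2,
                                seed = s * 1000 + i + (g == "MUT") * 500)
      pr <- state_time_profile(hyp, 12)
      rem <- pr$minutes[pr$state == "R"]
      vals <- c(vals, rem)
      gt <- c(gt, g, g)
      ph <- c(ph, "light", "dark")
    }
    fit <- two_way_anova(vals, gt, ph)
    p_int <- fit$anova$p[fit$anova$effect == "A:B"]
    hits <- hits + (p_int < 0.05)
  }
  expect_gte(hits / nseed, 0.8)
})

test_that("Sidak adjustment is exact, dominant and monotone in m", {
  expect_equal(sidak_adjust(0), 0)
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 24), 1 - 0.99^24, tolerance = 1e-15)
  set.seed(54)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 20) >= p))
  expect_true(all(sidak_adjust(p, 24) >= sidak_adjust(p, 20)))
  expect_true(all(sidak_adjust(p, 1000) <= 1))
  expect_error(sidak_adjust(1.2), "\\[0, 1\\]")
  expect_error(sidak_adjust(c(0.1, 0.2), 1), "family size")
})

test_that("Fisher LSD equals the pooled pairwise t in balanced designs", {
  expect_equal(fisher_lsd(c(a = 1, b = 1), c(a = 5, b = 5), 2, 8)$t, 0)
  # doubling MSE divides t by sqrt(2)
  l1 <- fisher_lsd(c(a = 1, b = 3), c(a = 6, b = 6), 1, 10)
  l2 <- fisher_lsd(c(a = 1, b = 3), c(a = 6, b = 6), 2, 10)
  expect_equal(l2$t, l1$t / sqrt(2), tolerance = 1e-12)
  # 2-cell oracle: LSD with the pooled variance is the pooled t-test
  set.seed(55)
  a <- rnorm(8); b <- rnorm(8, 1)
  mse <- (7 * var(a) + 7 * var(b)) / 14
  lsd <- fisher_lsd(c(a = mean(a), b = mean(b)), c(a = 8, b = 8), mse, 14)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(lsd$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(lsd$p, tt$p.value, tolerance = 1e-12)
  expect_error(fisher_lsd(c(a = 1, b = 2), c(a = 3, b = 3), 1, 4,
                          pairs = list(c("a", "z"))), "unknown cell")
})

test_that("normality and variance checks behave under null and violation", {
  set.seed(56)
  # Brown-Forsythe p-values approximately uniform under the null
  ps <- replicate(200, {
    normality_and_variance(list(a = rnorm(15), b = rnorm(15)))$brown_forsythe$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # power: one group at 4x SD, n = 30
  rej <- mean(replicate(50, {
    normality_and_variance(list(a = rnorm(30), b = rnorm(30, 0, 4)))$brown_forsythe$p < 0.05
  }))
  expect_gte(rej, 0.8)
  # constant group: Shapiro skipped with a flag
  nv <- normality_and_variance(list(a = rep(1, 10), b = rnorm(10)))
  expect_true(nv$shapiro$skipped[nv$shapiro$group == "a"])
  expect_false(nv$shapiro$skipped[nv$shapiro$group == "b"])
  nv2 <- normality_and_variance(list(a = rnorm(2), b = rnorm(10)))
  expect_true(nv2$shapiro$skipped[1])
})

test_that("type-I error sits at the nominal level on null simulations", {
  set.seed(57)
  n_rep <- 200
  rej <- mean(replicate(n_rep, unpaired_t(rnorm(12), rnorm(12))$p < 0.05))
  ci <- stats::binom.test(round(rej * n_rep), n_rep, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("group summaries report mean and SEM", {
  s <- group_summary(list(g = c(1, 2, 3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_true(is.na(group_summary(list(g = 5))$sem))
  set.seed(58)
  x <- rnorm(40)
  s2 <- group_summary(list(x = x))
  expect_equal(s2$sem, sd(x) / sqrt(40), tolerance = 1e-12)
})
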