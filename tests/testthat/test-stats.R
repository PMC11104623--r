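test_that("sign-flip permutation t-test behaves on degenerate and null inputs", {
  a <- c(1.2, 0.7, -0.3, 2.2, 0.5)
  # identical pairs: sign flips change nothing, p = 1
  res <- perm_ttest(a, a, paired = TRUE, n_perm = 499, seed = 1)
  expect_equal(res$p.value, 1)
  expect_equal(res$statistic, 0)
  # constant nonzero differences are degenerate
  expect_error(perm_ttest(a, a - 1, paired = TRUE), "zero variance")
  # symmetric null:
  set.seed(2)
  x <- rnorm(12)
  r0 <- perm_ttest(x, 0, n_perm = 999, seed = 3)
  expect_gt(r0$p.value, 0.05)
  expect_equal(r0$scheme, "sign-flip")
  # reproducible under the same seed, p never zero
  r1 <- perm_ttest(x, 0, n_perm = 999, seed = 3)
  expect_identical(r0$p.value, r1$p.value)
  expect_gt(r0$p.value, 0)
})

test_that("two-sample permutation t-test detects a large shift", {
  set.seed(4)
  a <- rnorm(20, 1.5); b <- rnorm(20, 0)
  r <- perm_ttest(a, b, n_perm = 999, seed = 5)
  expect_equal(r$scheme, "label-permutation")
  expect_lt(r$p.value, 0.01)
  r_less <- perm_ttest(a, b, alternative = "less", n_perm = 999, seed = 5)
  expect_gt(r_less$p.value, 0.95)
  expect_error(perm_ttest(1, c(1, 2)), "at least 2")
})

test_that("type-I error of the sign-flip test is near nominal", {
  set.seed(6)
  nsim <- 400
  rej <- 0
  for (i in seq_len(nsim)) {
    x <- rnorm(20)
    rej <- rej + (perm_ttest(x, 0, n_perm = 199)$p.value <= 0.05)
  }
  expect_gt(rej / nsim, 0.02)
  expect_lt(rej / nsim, 0.09)
})

test_that("Holm correction reproduces the step-down adjustment", {
  out <- holm_correct(c(0.01, 0.04, 0.03))
  expect_equal(out$p_adjusted, c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.02)$p_adjusted, 0.02)
  expect_equal(holm_correct(rep(1, 5))$p_adjusted, rep(1, 5))
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
  # never more liberal than Bonferroni, never more conservative than raw
  set.seed(7)
  p <- runif(20)
  h <- holm_correct(p)$p_adjusted
  expect_true(all(h <= pmin(p * length(p), 1) + 1e-12))
  expect_true(all(h >= p))
})

test_that("dip statistic matches the exhaustive small-n brute force", {
  # expected values computed once with an exact LP minimisation over
  # piecewise-linear unimodal CDFs and frozen here
  cases <- list(
    list(x = c(0, 1, 2, 10), d = 0.125),
    list(x = c(0.1, 0.4, 0.5, 0.9), d = 0.125),
    list(x = c(0, 0, 1, 1), d = 0.25),
    list(x = c(1, 2, 3, 4, 5), d = 0.1),
    list(x = c(0, 0.1, 0.2, 5, 5.1), d = 0.1),
    list(x = c(-3, -2.8, 0, 2.9, 3, 3.1), d = 0.155555555556),
    list(x = c(0, 1, 1, 2, 6, 7, 7), d = 0.142857142857),
    list(x = c(0.05, 0.1, 0.15, 0.5, 0.8, 0.85, 0.9, 0.95),
         d = 0.145833333333)
  )
  for (cs in cases) {
    expect_equal(dip_statistic(cs$x), cs$d, tolerance = 1e-6)
  }
})

test_that("dip statistic satisfies its known bounds", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- rnorm(n) # continuous, so values are distinct
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-10)
    expect_lte(d, 0.25 + 1e-10)
  }
  # equal two-point masses approach the upper bound
  expect_equal(dip_statistic(rep(c(0, 1), each = 50)), 0.25,
               tolerance = 1e-9)
  expect_error(dip_statistic(c(1, 2, 3)), "at least 4")
  expect_error(dip_statistic(c(1, 2, 3, NA)), "finite")
})

test_that("Monte-Carlo dip test separates unimodal from bimodal samples", {
  set.seed(9)
  uni <- rnorm(150)
  bim <- c(rnorm(75, -2, 0.5), rnorm(75, 2, 0.5))
  null_d <- dip_null(150, 199, seed = 10)
  t_uni <- dip_test(uni, null_dips = null_d)
  t_bim <- dip_test(bim, null_dips = null_d)
  expect_gt(t_uni$p.value, 0.05)
  expect_lt(t_bim$p.value, 0.01)
  # seed reproducibility and add-one p
  r1 <- dip_test(uni, n_mc = 99, seed = 11)
  r2 <- dip_test(uni, n_mc = 99, seed = 11)
  expect_identical(r1$p.value, r2$p.value)
  expect_gt(r1$p.value, 0)
})

test_that("learning trend test finds trends and handles separation", {
  set.seed(12)
  make_cohort <- function(beta) {
    do.call(rbind, lapply(1:12, function(p) {
      tc <- seq(-50, 50)
      pr <- 1 / (1 + exp(-(0 + beta * tc)))
      data.frame(participant = p, trial_c = tc,
                 outcome = rbinom(length(tc), 1, pr))
    }))
  }
  r_null <- learning_trend_test(make_cohort(0), n_perm = 499, seed = 13)
  expect_gt(r_null$p.value, 0.05)
  r_trend <- learning_trend_test(make_cohort(0.08), n_perm = 499, seed = 13)
  expect_lt(r_trend$p.value, 0.01)
  # perfectly monotone switch: separation -> penalized fallback, flagged,
  # positive slope (switch points differ so the group test is not degenerate)
  sep <- do.call(rbind, lapply(1:3, function(p) {
    data.frame(participant = p, trial_c = seq(-19.5, 19.5),
               outcome = as.integer(seq(-19.5, 19.5) > -5 + 5 * p))
  }))
  r_sep <- learning_trend_test(sep, n_perm = 199, seed = 14)
  expect_equal(sort(r_sep$flagged), 1:3)
  expect_true(all(r_sep$slopes$slope > 0))
  expect_error(learning_trend_test(sep[sep$participant == 1, ]),
               "2 participants")
})

test_that("mixed ANOVA F values match a textbook split-plot decomposition", {
  d <- mixed_fixture(phase_shift = 1, noise_sd = 0.4, seed = 15)
  res <- perm_mixed_anova(d, dv = "y", n_perm = 199, seed = 16)
  # independent oracle: classical sums of squares computed by hand
  Y <- with(d, tapply(y, list(participant, feedback, phase), mean))
  gm <- mean(d$y)
  subj_m <- apply(Y, 1, mean)
  grp <- c("motor-first", "motor-first", "action-first", "action-first")
  grp_m <- as.numeric(tapply(subj_m, grp, mean)[grp])
  ss_between <- 4 * sum((grp_m - gm)^2) # 4 = cells per participant
  ss_subj <- 4 * sum((subj_m - grp_m)^2)
  f_order <- (ss_between / 1) / (ss_subj / 2)
  expect_equal(res$table$F[res$table$effect == "order"], f_order,
               tolerance = 1e-8)
  # phase main effect against phase x subject error
  ph_m <- apply(Y, 3, mean)
  ss_phase <- 8 * sum((ph_m - gm)^2)
  cellsp <- apply(Y, c(1, 3), mean) # participant x phase
  grp_ph <- apply(cellsp, 2,
                  function(col) as.numeric(tapply(col, grp, mean)[grp]))
  ss_phase_subj <- 2 * sum((cellsp - subj_m - grp_ph + grp_m)^2)
  f_phase <- (ss_phase / 1) / (ss_phase_subj / 2)
  expect_equal(res$table$F[res$table$effect == "phase"], f_phase,
               tolerance = 1e-8)
})

test_that("mixed ANOVA detects an injected within effect at cohort size", {
  d <- mixed_fixture(phase_shift = 1, noise_sd = 0.4, seed = 18,
                     n_per_group = 11)
  res <- perm_mixed_anova(d, dv = "y", n_perm = 399, seed = 19)
  expect_lt(res$table$p_perm[res$table$effect == "phase"], 0.05)
  # effects that were not injected stay non-significant
  expect_gt(res$table$p_perm[res$table$effect == "order"], 0.05)
})

test_that("mixed ANOVA rejects unbalanced designs and degenerate data", {
  d <- mixed_fixture()
  expect_error(perm_mixed_anova(d[-1, ], dv = "y"), "unbalanced")
  d_extra <- rbind(d, d[d$participant == 1, ][1, ])
  expect_error(perm_mixed_anova(d_extra, dv = "y"), "unbalanced")
  d_uneq <- d
  d_uneq$order[d_uneq$participant == 2] <- "action-first"
  expect_error(perm_mixed_anova(d_uneq, dv = "y"), "equal size")
  d_const <- d; d_const$y <- 2
  res <- perm_mixed_anova(d_const, dv = "y", n_perm = 99, seed = 17)
  expect_true(all(res$table$F == 0))
  expect_true(all(res$table$p_perm == 1))
})
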