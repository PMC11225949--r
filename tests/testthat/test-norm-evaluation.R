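test_that("maladjustment regression flags injected demographic trends", {
  set.seed(901)
  d <- gen_demographics(simulation_spec(n = 1000, seed = 902))
  # T-scores independent of demographics: nothing should be flagged often
  t_null <- data.frame(cwit1 = rnorm(1000, 50, 10))
  rep0 <- maladjustment_regression(t_null, d)
  expect_true(all(c("age", "edu", "female") %in% rep0$predictor))
  # +0.05 * age trend is reliably detected at n = 1000
  t_age <- data.frame(cwit1 = rnorm(1000, 50, 10) + 0.05 * (d$age - 46.2))
  hits <- 0
  for (i in 1:20) {
    t_age$cwit1 <- rnorm(1000, 50, 10) + 0.05 * (d$age - 46.2)
    rep1 <- maladjustment_regression(t_age, d)
    if (rep1$flagged[rep1$predictor == "age"]) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_error(maladjustment_regression(data.frame(cwit1 = rnorm(20)),
                                        d[1:20, ]), ">= 50")
})

test_that("scoring a cohort with its generating norms shows no maladjustment", {
  spec <- simulation_spec(n = 20000, seed = 903)
  d <- gen_cwit_times(gen_demographics(spec), spec$norms, seed = 904)
  sc <- score_batch(norwegian_norms(), d)
  t3 <- sc[sc$subtest == "cwit3", ]
  rep <- maladjustment_regression(
    data.frame(cwit3 = t3$t),
    data.frame(age = t3$age, education = t3$education, sex = t3$sex))
  # effect sizes are negligible even if huge n makes p-values twitchy
  slopes <- rep$b[rep$predictor %in% c("age", "edu")]
  expect_true(all(abs(slopes) < 0.03))
  expect_true(all(rep$partial_r2[rep$predictor != "intercept"] < 0.002))
})

test_that("paired norm comparisons match the closed-form paired t", {
  a <- c(51, 52, 53)
  b <- a - c(1, 2, 3)
  res <- paired_norm_comparison(a, b)
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 2 / (1 / sqrt(3)))  # mean 2, SD 1, n 3
  expect_equal(res$cohens_d, 2)
  same <- paired_norm_comparison(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(paired_norm_comparison(1:3, 1:4), "equal length")
  # a +3 T offset between normsets is estimated as ~3
  set.seed(905)
  t1 <- rnorm(500, 50, 10)
  res3 <- paired_norm_comparison(t1 + 3 + rnorm(500, 0, 1), t1)
  expect_lt(abs(res3$mean_diff - 3), 0.2)
})

test_that("base-rate analysis: expected rate, z and Wilson CI", {
  # the theoretical base rate below -1.5 SD prints as 6.7%
  expect_equal(round(100 * pnorm(-1.5), 1), 6.7)
  # a sample at exactly the expected rate has |z| ~ 0
  set.seed(906)
  t <- rnorm(1000, 50, 10)
  cut <- quantile(t, pnorm(-1.5))
  res <- base_rate_analysis(t, cutoff_t = cut)
  expect_lt(abs(res$z), 0.15)
  # Wilson CI matches prop.test's score interval (no continuity correction)
  for (case in list(c(1011, 87), c(200, 5), c(50, 10))) {
    n <- case[1]; x <- case[2]
    ours <- wilson_ci(x, n, 0.99)
    ref <- prop.test(x, n, conf.level = 0.99, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
  # the published low-score count on word reading: 87/1011 = 8.6%
  res2 <- base_rate_analysis(c(rep(30, 87), rep(50, 1011 - 87)))
  expect_equal(round(res2$proportion_pct, 1), 8.6)
  expect_equal(res2$count_below, 87)
  expect_true(res2$ci_lo_pct < 8.6 & 8.6 < res2$ci_hi_pct)
})

test_that("McNemar: closed form, degenerate case and concordance invariance", {
  a <- c(rep(TRUE, 5), rep(FALSE, 1), rep(TRUE, 10), rep(FALSE, 10))
  b <- c(rep(FALSE, 5), rep(TRUE, 1), rep(TRUE, 10), rep(FALSE, 10))
  res <- mcnemar_paired(a, b)
  expect_equal(res$b, 5)
  expect_equal(res$c, 1)
  expect_equal(res$chi_square, (5 - 1)^2 / 6)
  expect_equal(res$p, pchisq(16 / 6, 1, lower.tail = FALSE))
  # matches stats::mcnemar.test without continuity correction
  ref <- mcnemar.test(table(a, b), correct = FALSE)
  expect_equal(res$chi_square, unname(ref$statistic))
  # identical flags: degenerate, p = 1 with note
  same <- mcnemar_paired(a, a)
  expect_equal(same$p, 1)
  expect_match(same$note, "degenerate")
  # invariant to adding concordant pairs
  res2 <- mcnemar_paired(c(a, TRUE, TRUE, FALSE), c(b, TRUE, TRUE, FALSE))
  expect_equal(res2$chi_square, res$chi_square)
})

test_that("self-scored low-score rates stay within the 99% band up to discretization", {
  # under correctly specified norms the observed T < 35 rate should sit
  # inside the 99% sampling band around 6.7%, widened by the documented
  # +/- 0.6 pp bias that integer scaled scores introduce near the cutoff
  spec <- simulation_spec(n = 100000, seed = 909)
  d <- gen_cwit_times(gen_demographics(spec), spec$norms, seed = 910)
  sc <- score_batch(norwegian_norms(), d)
  expected <- pnorm(-1.5)
  half <- qnorm(0.995) * sqrt(expected * (1 - expected) / 100000)
  for (st in unique(sc$subtest)) {
    rate <- mean(sc$t[sc$subtest == st] < 35)
    expect_lt(abs(rate - expected), half + 0.006,
              label = paste(st, "low-score rate"))
  }
})

test_that("biased norms are caught by the base-rate machinery", {
  spec <- simulation_spec(n = 1011, seed = 907)
  d <- gen_cwit_times(gen_demographics(spec), spec$norms, seed = 908)
  nor <- norwegian_norms()
  sc <- score_batch(nor, d)
  t3 <- sc$t[sc$subtest == "cwit3"]
  flags_true <- t3 < 35
  flags_biased <- (t3 + 3) < 35  # +3 T bias hides low scorers
  mcn <- mcnemar_paired(flags_biased, flags_true)
  expect_lt(mcn$p, 0.01)
  expect_lt(sum(flags_biased), sum(flags_true))
})
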