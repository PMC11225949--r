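test_that("generated demographics match the normative sample's marginals", {
  spec <- simulation_spec(n = 10000, seed = 501)
  d <- gen_demographics(spec)
  expect_true(all(d$age >= 20 & d$age <= 85))
  expect_true(all(d$education >= 7 & d$education <= 23))
  expect_true(is.integer(d$education))
  expect_lt(abs(mean(d$age) - 46.2), 1.0)
  expect_lt(abs(sd(d$age) - 19.4), 1.0)
  expect_lt(abs(mean(d$education) - 15.5), 0.1)
  expect_lt(abs(100 * mean(d$sex == "female") - 66.8), 1.5)
  # single record is in range
  one <- gen_demographics(simulation_spec(n = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_true(one$age >= 20 && one$age <= 85)
})

test_that("generation is deterministic given the seed", {
  spec <- simulation_spec(n = 200, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_spec(n = 200, seed = 100))
  expect_false(identical(a$cwit1_time, c2$cwit1_time))
})

test_that("every generated raw time maps back to its generating scaled score", {
  spec <- simulation_spec(n = 3000, seed = 502)
  d <- gen_cwit_times(gen_demographics(spec), spec$norms, seed = 503)
  lat <- attr(d, "latent")
  for (st in c("cwit1", "cwit2", "cwit3", "cwit4")) {
    li <- lat[lat$subtest == st, ]
    expect_equal(raw_to_scaled(spec$norms$tables[[st]],
                               d[[paste0(st, "_time")]]),
                 li$scaled, info = st)
  }
  # latent scaled scores only take values present in each table
  expect_true(all(lat$scaled[lat$subtest == "cwit2"] %in%
                    spec$norms$tables$cwit2$bins$scaled))
})

test_that("zero residual SD pins the latent score to the prediction", {
  nor <- norwegian_norms()
  eq <- nor$equations$cwit1
  eq$sd_residual <- 1e-9
  ns <- normset("degenerate", list(cwit1 = eq), nor$tables["cwit1"])
  d <- data.frame(id = c("A", "B"), age = c(46.2, 46.2),
                  education = c(15.5, 15.5),
                  sex = factor(c("male", "male"), c("male", "female")))
  g <- gen_cwit_times(d, ns, seed = 1)
  lat <- attr(g, "latent")
  expect_equal(lat$latent, rep(eq$intercept, 2), tolerance = 1e-6)
})

test_that("latent score variance follows the law of total variance", {
  spec <- simulation_spec(n = 10000, seed = 504)
  d <- gen_cwit_times(gen_demographics(spec), spec$norms, seed = 505)
  lat <- attr(d, "latent")
  li <- lat[lat$subtest == "cwit1", ]
  expected <- 2.775^2 + var(li$predicted)
  expect_lt(abs(var(li$latent) - expected) / expected, 0.05)
})

test_that("error generator is calibrated to the published cumulative table", {
  spec <- simulation_spec(n = 100000, seed = 506)
  d <- gen_errors(gen_demographics(spec), seed = 507)
  pub <- norwegian_error_percentages()
  for (st in c("cwit3", "cwit4")) {
    e <- d[[paste0(st, "_errors")]]
    expect_true(all(e >= 0) && all(e == floor(e)))
    for (k in 1:6) {
      expect_lt(abs(100 * mean(e >= k) - pub[[st]][pub$errors == k]), 1.0,
                label = sprintf("%s cumulative at k=%d", st, k))
    }
  }
  # degenerate hurdle: no positive mass means all zeros
  z <- gen_errors(gen_demographics(simulation_spec(n = 50, seed = 1)),
                  error_models = list(cwit3 = c(p_pos = 0, size = 1, mu = 1)),
                  seed = 2)
  expect_true(all(z$cwit3_errors == 0))
})

test_that("retest arm induces the target ICC and exercises the filter", {
  nor <- norwegian_norms()
  # near-perfect latent correlation, no practice: follow-up == baseline scaled
  spec <- simulation_spec(
    n = 400, seed = 508,
    retest = list(target_icc = c(cwit1 = .999, cwit2 = .999, cwit3 = .999,
                                 cwit4 = .999),
                  practice = 0,
                  interval = list(mean = 3.4, sd = 0.9, range = c(1, 5)),
                  p_overlimit = 0))
  d <- gen_cwit_times(gen_demographics(spec), nor, seed = 509)
  lng <- gen_retest(d, spec, seed = 510)
  lat <- attr(d, "latent")
  s1 <- lat$scaled[lat$subtest == "cwit3"]
  s2 <- raw_to_scaled(nor$tables$cwit3, lng$cwit3_time_fu)
  expect_gt(mean(s1 == s2), 0.95)
  expect_true(all(lng$interval_years >= 1 & lng$interval_years <= 5))
  expect_lt(abs(mean(lng$interval_years) - 3.4), 0.3)
  # over-limit intervals appear when requested and get filtered downstream
  spec2 <- spec
  spec2$retest$p_overlimit <- 0.1
  lng2 <- gen_retest(d, spec2, seed = 511)
  expect_gt(sum(lng2$interval_years > 5), 0)
  flt <- filter_retest(lng2, 5)
  expect_equal(nrow(flt$retained) + flt$excluded, nrow(lng2))
  expect_true(all(flt$retained$interval_years <= 5))
})

test_that("hurdle error-model fit reproduces its calibration targets", {
  pub <- norwegian_error_percentages()
  for (st in c("cwit3", "cwit4")) {
    par <- fit_error_model(pub[[st]][pub$errors >= 1])
    expect_equal(unname(par[["p_pos"]]), pub[[st]][pub$errors == 1] / 100)
    s <- pnbinom(0:5, size = par[["size"]], mu = par[["mu"]],
                 lower.tail = FALSE)
    model_cum <- 100 * par[["p_pos"]] * s / s[1]
    expect_lt(max(abs(model_cum - pub[[st]][pub$errors %in% 1:6])), 0.5)
  }
})
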