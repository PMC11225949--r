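test_that("design rows center demographics and form interaction products", {
  X <- design_matrix(46.2, 15.5, "male")
  expect_true(all(X == 0))
  X2 <- design_matrix(70, 17, "male", c("age", "age2"))
  expect_equal(unname(X2[1, ]), c(23.8, 23.8^2))
  X3 <- design_matrix(50, 15.5, "female", c("age", "female", "age:female"))
  expect_equal(unname(X3[1, "age:female"]), 3.8)
  expect_error(design_matrix(NA, 15, "male"), "missing")
  expect_error(design_matrix(50, 15, "male", "bogus"), "unknown term")
})

test_that("OLS matches the normal-equations oracle and degenerate cases", {
  set.seed(601)
  for (rep in 1:5) {
    n <- 40
    X <- design_matrix(runif(n, 20, 85), sample(7:23, n, TRUE),
                       sample(c("male", "female"), n, TRUE),
                       c("age", "age2", "edu", "female", "age:female"))
    y <- 10 - 0.05 * X[, "age"] + 0.1 * X[, "edu"] + rnorm(n, 0, 2)
    fit <- fit_ols(X, y)
    orc <- oracle_ols(X, y)
    expect_equal(fit$coefficients$b, unname(orc$b), tolerance = 1e-8)
    expect_equal(fit$coefficients$se, unname(orc$se), tolerance = 1e-8)
    expect_equal(fit$sd_residual, orc$sd_residual, tolerance = 1e-8)
    # partial R2 identity per term
    expect_equal(fit$coefficients$partial_r2,
                 fit$coefficients$t^2 / (fit$coefficients$t^2 + fit$df_residual))
  }
  # exact linear response: zero residual SD, R2 = 1
  X <- design_matrix(c(30, 40, 50, 60, 70, 25), c(10, 12, 14, 16, 18, 20),
                     rep("male", 6), c("age", "edu"))
  y <- 5 + 0.2 * X[, "age"] - 0.3 * X[, "edu"]
  fit <- suppressWarnings(fit_ols(X, y))  # lm warns on exact fits
  expect_lt(fit$sd_residual, 1e-10)
  expect_equal(fit$r2, 1)
  # rank deficiency names the offending column
  Xc <- cbind(X, dup = X[, "age"])
  expect_error(fit_ols(Xc, y), "collinear")
})

test_that("partial R2 from printed t and df reproduces the published values", {
  expect_equal(round((-15.97)^2 / ((-15.97)^2 + 1006), 3), 0.202)
  expect_equal(round((-13.83)^2 / ((-13.83)^2 + 1007), 3), 0.160)
})

test_that("stepwise selection respects marginality and drops null structure", {
  nor <- norwegian_norms()
  spec <- simulation_spec(n = 5000, seed = 602)
  d <- gen_cwit_times(gen_demographics(spec), nor, seed = 603)
  d$resp <- raw_to_scaled(nor$tables$cwit4, d$cwit4_time)
  sel <- select_model(d, "resp", centering = c(age = 46.2, edu = 15.5))
  # generating structure for this subtest: age + age2 + edu
  expect_setequal(sel$terms, c("age", "age2", "edu"))
  # trace records only admissible decisions
  expect_true(all(sel$trace$decision %in% c("dropped", "retained")))
  expect_true(all(sel$trace$p[sel$trace$decision == "dropped"] >= 0.01))
  # no model along the way may contain a term without its required mains:
  # the endpoint must satisfy marginality
  for (tm in sel$terms) {
    expect_true(all(cwitnorms:::term_requires(tm) %in% sel$terms))
  }
})

test_that("selection removes education terms when education has no effect", {
  nor <- norwegian_norms()
  spec <- simulation_spec(n = 5000, seed = 604)
  d <- gen_cwit_times(gen_demographics(spec), nor, seed = 605)
  # cwit1 generating equation has no education terms
  d$resp <- raw_to_scaled(nor$tables$cwit1, d$cwit1_time)
  sel <- select_model(d, "resp", centering = c(age = 46.2, edu = 15.5))
  expect_false(any(grepl("edu", sel$terms)))
  expect_setequal(sel$terms, c("age", "age2", "female"))
})

test_that("pure-noise responses mostly reduce to the intercept-only model", {
  set.seed(606)
  hits <- 0
  for (i in 1:20) {
    d <- gen_demographics(simulation_spec(n = 400, seed = 700 + i))
    d$resp <- rnorm(nrow(d), 10, 3)
    sel <- select_model(d, "resp")
    if (length(sel$terms) == 0) hits <- hits + 1
  }
  # ~10 independent alpha=.01 chances to keep something spurious per run
  expect_gte(hits, 14)
})

test_that("diagnostics flag gross outliers and stay quiet for perfect fits", {
  X <- design_matrix(c(30, 40, 50, 60, 70, 25), c(10, 12, 14, 16, 18, 20),
                     rep("male", 6), c("age"))
  y <- 5 + 0.2 * X[, "age"]
  dg <- ols_diagnostics(suppressWarnings(fit_ols(X, y)))
  expect_true(all(dg$residuals$cooks_d == 0))
  set.seed(607)
  n <- 30
  X <- design_matrix(runif(n, 20, 85), sample(7:23, n, TRUE),
                     rep("male", n), "age")
  y <- 10 - 0.05 * X[, "age"] + rnorm(n, 0, 0.5)
  y[7] <- y[7] + 25
  dg <- ols_diagnostics(fit_ols(X, y))
  expect_equal(which.max(dg$residuals$cooks_d), 7)
  # homoscedastic residuals: |cor(|res|, fitted)| small on average
  expect_lt(abs(dg$het_cor), 0.6)
})

test_that("extracted equations are self-contained and refit to themselves", {
  nor <- norwegian_norms()
  spec <- simulation_spec(n = 10000, seed = 608)
  d <- gen_cwit_times(gen_demographics(spec), nor, seed = 609)
  s <- raw_to_scaled(nor$tables$cwit1, d$cwit1_time)
  gen <- nor$equations$cwit1
  X <- design_matrix(d$age, d$education, d$sex, names(gen$coefficients),
                     gen$centering)
  fit <- fit_ols(X, s)
  eq <- extract_equation(fit, "cwit1", gen$centering)
  # recovery of the generating intercept within 2 SE
  expect_lt(abs(eq$intercept - gen$intercept),
            2 * fit$coefficients$se[fit$coefficients$term == "intercept"])
  # refitting on the equation's own predictions gives an exact fit
  yhat <- predict_scaled(eq, d$age, d$education, d$sex)
  refit <- extract_equation(suppressWarnings(fit_ols(X, yhat)), "cwit1",
                            gen$centering)
  expect_equal(refit$coefficients, eq$coefficients, tolerance = 1e-8)
  expect_lt(refit$sd_residual, 1e-8)
})

test_that("SUR reduces to OLS with identical regressors and tests equality", {
  nor <- norwegian_norms()
  spec <- simulation_spec(n = 2000, seed = 610)
  d <- gen_cwit_times(gen_demographics(spec), nor, seed = 611)
  d$s2 <- raw_to_scaled(nor$tables$cwit2, d$cwit2_time)
  d$s3 <- raw_to_scaled(nor$tables$cwit3, d$cwit3_time)
  ctr <- c(age = 46.2, edu = 15.5)
  sur <- fit_sur(d, "s2", "s3", c("age", "age2"), c("age", "age2"), ctr)
  ols <- fit_ols(design_matrix(d$age, d$education, d$sex, c("age", "age2"),
                               ctr), d$s2)
  expect_equal(unname(sur$b1), ols$coefficients$b, tolerance = 1e-10)
  # self-comparison: identical responses give diff 0, z 0
  self <- test_equality(d, "s3", "s3", c("age", "age2"), c("age", "age2"),
                        term = "age", centering = ctr)
  expect_equal(self$diff, 0, tolerance = 1e-12)
  expect_equal(self$z, 0, tolerance = 1e-6)
  # generating age slopes -0.019 vs -0.073 are told apart at alpha = .01
  eqt <- test_equality(d, "s2", "s3", c("age", "age2"),
                       c("age", "age2", "edu", "female"), term = "age",
                       centering = ctr)
  expect_lt(eqt$p, 0.01)
  expect_gt(eqt$diff, 0)  # age effect weaker (less negative) on word reading
  expect_error(test_equality(d, "s2", "s3", c("age"), c("edu"), term = "age"),
               "both equations")
})
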