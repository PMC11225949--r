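# shared fixtures built in code

toy_cohort <- function() {
  data.frame(
    id = c("P1", "P2", "P3"),
    age = c(70, 55, 30),
    education = c(17, 12, 16),
    sex = factor(c("male", "female", "female"), levels = c("male", "female")),
    cwit1_time = c(35, 28, 24),
    cwit2_time = c(25, 21, 18),
    cwit3_time = c(60, 78, 40),
    cwit4_time = c(70, 85, 45),
    cwit3_errors = c(0, 2, NA),
    cwit4_errors = c(1, 4, NA),
    mmse = c(29, NA, 30)
  )
}

# brute-force OLS by the normal equations, for use as an independent oracle
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  b <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  res <- y - Xi %*% b
  dfres <- length(y) - ncol(Xi)
  s2 <- sum(res^2) / dfres
  V <- s2 * solve(t(Xi) %*% Xi)
  list(b = drop(b), se = sqrt(diag(V)), sd_residual = sqrt(s2))
}

# brute-force midpoint percentile of one value within a sample
oracle_percentile <- function(v, sample) {
  100 * (sum(sample > v) + sum(sample == v) / 2) / length(sample)
}
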