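# Auditing a norm set against a cohort: if norms adjust demographics
# correctly, T-scores are unrelated to age, education and sex, average 50,
# and put ~6.7% of a healthy sample below T = 35 (1.5 SD below the mean).

#' Maladjustment regression of T-scores on demographics
#'
#' One OLS per subtest of T-scores on mean-centered age, mean-centered
#' education and sex; a significant predictor flags residual demographic
#' structure the norms failed to remove.
#'
#' @param tscores data.frame of T-score columns, one per subtest (NAs
#'   allowed).
#' @param demographics data.frame with `age`, `education`, `sex` row-aligned
#'   with `tscores`.
#' @param alpha evaluation alpha (default .05).
#' @return data.frame: subtest, predictor, b, se, p, partial_r2, adj_r2,
#'   flagged.
#' @export
maladjustment_regression <- function(tscores, demographics, alpha = 0.05) {
  one <- function(st) {
    y <- tscores[[st]]
    ok <- !is.na(y)
    stop_if_not(sum(ok) >= 50, "need >= 50 complete cases for ", st)
    X <- design_matrix(demographics$age[ok], demographics$education[ok],
                       demographics$sex[ok], c("age", "edu", "female"),
                       centering = c(age = mean(demographics$age[ok]),
                                     edu = mean(demographics$education[ok])))
    fit <- fit_ols(X, y[ok])
    cf <- fit$coefficients
    data.frame(subtest = st, predictor = cf$term, b = cf$b, se = cf$se,
               p = cf$p, partial_r2 = cf$partial_r2, adj_r2 = fit$adj_r2,
               flagged = cf$term != "intercept" & cf$p < alpha)
  }
  out <- do.call(rbind, lapply(names(tscores), one))
  rownames(out) <- NULL
  out
}

#' Paired comparison of two norm sets' T-scores
#'
#' Paired t-test of the per-person difference in T-scores under two norm
#' sets, with Cohen's d = mean difference / SD of differences.
#'
#' @param tscoresA,tscoresB numeric vectors of T-scores for the same
#'   participants in the same order.
#' @return data.frame: n, mean_a, mean_b, mean_diff, ci_lo, ci_hi, t, df,
#'   p, cohens_d.
#' @export
paired_norm_comparison <- function(tscoresA, tscoresB) {
  stop_if_not(length(tscoresA) == length(tscoresB),
              "paired vectors must have equal length")
  ok <- !is.na(tscoresA) & !is.na(tscoresB)
  a <- tscoresA[ok]
  b <- tscoresB[ok]
  d <- a - b
  if (stats::sd(d) == 0) {
    return(data.frame(n = length(d), mean_a = mean(a), mean_b = mean(b),
                      mean_diff = mean(d), ci_lo = mean(d), ci_hi = mean(d),
                      t = 0, df = length(d) - 1, p = 1, cohens_d = 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(n = length(d), mean_a = mean(a), mean_b = mean(b),
             mean_diff = mean(d), ci_lo = tt$conf.int[1],
             ci_hi = tt$conf.int[2], t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             cohens_d = mean(d) / stats::sd(d))
}

#' Wilson score confidence interval for a proportion
#'
#' @param count number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.99).
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(count, n, conf = 0.99) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- count / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = center - half, upper = center + half)
}

#' Low-score base-rate analysis
#'
#' Compares the observed proportion of participants scoring strictly below a
#' T cutoff with the base rate expected under normality (6.7% below
#' -1.5 SD), via a two-sided one-proportion Z-test without continuity
#' correction and a Wilson score 99% CI around the sample proportion.
#'
#' @param tscores numeric vector of T-scores (NAs dropped).
#' @param cutoff_t low-score cutoff (default 35, i.e. 1.5 SD below 50).
#' @param expected expected proportion (default `pnorm(-1.5)`).
#' @param conf confidence level of the reported CI (default 0.99).
#' @return data.frame: n, count_below, proportion_pct, ci_lo_pct,
#'   ci_hi_pct, expected_pct, z, p, covers_expected.
#' @export
base_rate_analysis <- function(tscores, cutoff_t = 35,
                               expected = stats::pnorm(-1.5), conf = 0.99) {
  x <- tscores[!is.na(tscores)]
  n <- length(x)
  stop_if_not(n >= 30, "need n >= 30 for the normal-approximation Z-test")
  count <- sum(x < cutoff_t)
  phat <- count / n
  z <- (phat - expected) / sqrt(expected * (1 - expected) / n)
  ci <- wilson_ci(count, n, conf)
  data.frame(n = n, count_below = count, proportion_pct = 100 * phat,
             ci_lo_pct = 100 * ci[["lower"]], ci_hi_pct = 100 * ci[["upper"]],
             expected_pct = 100 * expected, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             covers_expected = ci[["lower"]] <= expected &
               expected <= ci[["upper"]])
}

#' Asymptotic McNemar test without continuity correction
#'
#' Chi-square `(b - c)^2 / (b + c)` on the discordant pair counts of two
#' paired binary flag vectors, 1 df. When there are no discordant pairs the
#' statistic is undefined and `p = 1` is reported with a note.
#'
#' @param flagsA,flagsB logical vectors (same participants, same order).
#' @return data.frame: b, c, chi_square, p, note.
#' @export
mcnemar_paired <- function(flagsA, flagsB) {
  stop_if_not(length(flagsA) == length(flagsB),
              "paired flag vectors must have equal length")
  ok <- !is.na(flagsA) & !is.na(flagsB)
  a <- flagsA[ok]
  bb <- flagsB[ok]
  b <- sum(a & !bb)
  cc <- sum(!a & bb)
  if (b + cc == 0) {
    return(data.frame(b = b, c = cc, chi_square = NA_real_, p = 1,
                      note = "no discordant pairs; test degenerate"))
  }
  chi <- (b - cc)^2 / (b + cc)
  data.frame(b = b, c = cc, chi_square = chi,
             p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
             note = "")
}
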