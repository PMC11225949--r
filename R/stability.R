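# Test-retest stability of normed CWIT scores: interval filtering, ICC of
# the single-rating absolute-agreement two-way mixed-effects form, and
# reliable change indices.

#' Filter retest pairs by maximum interval
#'
#' @param pairs data.frame with an `interval_years` column.
#' @param max_interval maximum admissible test-retest interval in years
#'   (default 5).
#' @return list with `retained` (data.frame) and `excluded` (count).
#' @export
filter_retest <- function(pairs, max_interval = 5) {
  stop_if_not("interval_years" %in% names(pairs),
              "pairs need an interval_years column")
  stop_if_not(all(pairs$interval_years > 0, na.rm = TRUE),
              "intervals must be positive")
  keep <- !is.na(pairs$interval_years) & pairs$interval_years <= max_interval
  list(retained = pairs[keep, , drop = FALSE], excluded = sum(!keep))
}

#' ICC(A,1): single-rating absolute-agreement two-way mixed-effects model
#'
#' Two-way ANOVA decomposition over subjects (rows) and occasions (columns):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#' F-distribution confidence interval of McGraw and Wong for the
#' absolute-agreement single-rating case.
#'
#' @param baseline,followup numeric score vectors (complete pairs used).
#' @param conf confidence level (default 0.95).
#' @return data.frame: icc, ci_lo, ci_hi, msr, msc, mse, n, k.
#' @export
icc_a1 <- function(baseline, followup, conf = 0.95) {
  ok <- !is.na(baseline) & !is.na(followup)
  x <- cbind(baseline[ok], followup[ok])
  n <- nrow(x)
  k <- 2
  stop_if_not(n >= 5, "need at least 5 complete pairs")
  stop_if_not(stats::sd(rowMeans(x)) > 0, "no between-subject variance; ICC degenerate")
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw & Wong F-based CI for ICC(A,1)
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {  # perfect agreement
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fu <- stats::qf(1 - alpha / 2, n - 1, v)
    fl <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fu * mse) /
      (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fl * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fl * msr)
    ci <- c(lower, upper)
  }
  data.frame(icc = icc, ci_lo = ci[1], ci_hi = ci[2], msr = msr, msc = msc,
             mse = mse, n = n, k = k)
}

#' Reliable change index
#'
#' Standardizes a baseline-to-follow-up change score by the standard error
#' of the measurement difference. Methods: `jacobson_truax`
#' (`SEM = sd_baseline * sqrt(1 - r12)`, `SEdiff = sqrt(2) * SEM`,
#' `RCI = (follow - base) / SEdiff`), `practice_adjusted` (subtracts the
#' mean practice effect from the change first), and `regression_based`
#' (`RCI = (follow - (slope * base + intercept)) / see`).
#'
#' @param baseline,followup scores at the two occasions.
#' @param method one of `"jacobson_truax"`, `"practice_adjusted"`,
#'   `"regression_based"`.
#' @param sd_baseline baseline SD of the reference sample.
#' @param r12 test-retest correlation in (0, 1).
#' @param mean_practice mean practice effect (required for
#'   `practice_adjusted`).
#' @param slope,intercept,see regression of follow-up on baseline in the
#'   reference sample and its standard error of estimate (required for
#'   `regression_based`).
#' @param criterion significance criterion on the standardized change
#'   (default 1.96).
#' @return data.frame: method, change, statistic, significant.
#' @export
rci <- function(baseline, followup,
                method = c("jacobson_truax", "practice_adjusted",
                           "regression_based"),
                sd_baseline = NULL, r12 = NULL, mean_practice = NULL,
                slope = NULL, intercept = NULL, see = NULL,
                criterion = 1.96) {
  method <- match.arg(method)
  change <- followup - baseline
  if (method %in% c("jacobson_truax", "practice_adjusted")) {
    stop_if_not(!is.null(sd_baseline) && !is.null(r12),
                "sd_baseline and r12 are required")
    stop_if_not(r12 > 0 && r12 < 1, "r12 must be in (0, 1)")
    sediff <- sqrt(2) * sd_baseline * sqrt(1 - r12)
    adj <- if (method == "practice_adjusted") {
      stop_if_not(!is.null(mean_practice), "mean_practice is required")
      mean_practice
    } else 0
    stat <- (change - adj) / sediff
  } else {
    stop_if_not(!is.null(slope) && !is.null(intercept) && !is.null(see),
                "slope, intercept and see are required")
    stat <- (followup - (slope * baseline + intercept)) / see
  }
  data.frame(method = method, change = change, statistic = stat,
             significant = abs(stat) > criterion)
}

#' Per-subtest stability report on normed scores
#'
#' Scores baseline and follow-up times of a longitudinal cohort with the
#' supplied norm set(s), applies the retest-interval filter, and reports the
#' ICC(A,1) per subtest together with the descriptive statistics needed to
#' compute reliable change indices (baseline/follow-up means and SDs and
#' the Pearson retest correlation).
#'
#' @param cohort longitudinal-schema cohort data.frame.
#' @param norms a [normset()] or named list of normsets (one ICC row per
#'   normset and subtest).
#' @param max_interval retest-interval filter in years (default 5).
#' @param metric `"t"` to compute on demographically adjusted T-scores
#'   (default) or `"scaled"` for unadjusted scaled scores.
#' @return list with `icc` (data.frame), `rci_materials` (data.frame) and
#'   `excluded` (count filtered out by interval).
#' @export
stability_report <- function(cohort, norms, max_interval = 5,
                             metric = c("t", "scaled")) {
  metric <- match.arg(metric)
  stop_if_not(any(grepl("_time_fu$", names(cohort))),
              "cohort lacks follow-up time columns; not longitudinal")
  normsets <- if (inherits(norms, "cwit_normset")) {
    stats::setNames(list(norms), norms$label)
  } else norms
  flt <- filter_retest(cohort, max_interval)
  dat <- flt$retained
  icc_rows <- list()
  mat_rows <- list()
  for (lab in names(normsets)) {
    ns <- normsets[[lab]]
    for (st in names(ns$equations)) {
      b_raw <- dat[[paste0(st, "_time")]]
      f_raw <- dat[[paste0(st, "_time_fu")]]
      ok <- !is.na(b_raw) & !is.na(f_raw)
      if (sum(ok) < 5) next
      if (metric == "t") {
        b <- score_cwit(ns, st, b_raw[ok], dat$age[ok], dat$education[ok],
                        dat$sex[ok])$t
        f <- score_cwit(ns, st, f_raw[ok], dat$age[ok], dat$education[ok],
                        dat$sex[ok])$t
      } else {
        b <- raw_to_scaled(ns$tables[[st]], b_raw[ok])
        f <- raw_to_scaled(ns$tables[[st]], f_raw[ok])
      }
      ic <- icc_a1(b, f)
      icc_rows[[length(icc_rows) + 1]] <-
        cbind(data.frame(normset = lab, subtest = st), ic)
      mat_rows[[length(mat_rows) + 1]] <- data.frame(
        normset = lab, subtest = st, n = sum(ok),
        mean_baseline = mean(b), sd_baseline = stats::sd(b),
        mean_followup = mean(f), sd_followup = stats::sd(f),
        r12 = stats::cor(b, f), mean_practice = mean(f - b))
    }
  }
  list(icc = do.call(rbind, icc_rows),
       rci_materials = do.call(rbind, mat_rows),
       excluded = flt$excluded)
}
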