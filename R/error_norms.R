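# Normative treatment of CWIT-3/4 error counts. Errors are zero-inflated
# and over-dispersed and only weakly related to demographics, so they are
# normed as unstratified cumulative percentiles rather than by regression.

#' Cumulative error-count table
#'
#' `cumulative(k) = 100 * #\{errors >= k\} / n_available` for each error
#' count up to the observed maximum; missing values are excluded and
#' counted.
#'
#' @param errors integer vector of total error counts (NA = not recorded).
#' @param subtest subtest key (label only).
#' @return object of class `cwit_error_table`: data.frame `errors`,
#'   `cumulative_pct`, plus attributes `subtest`, `n_available`,
#'   `n_missing`.
#' @export
cumulative_error_table <- function(errors, subtest = "cwit3") {
  x <- errors[!is.na(errors)]
  stop_if_not(length(x) >= 1, "no non-missing error counts")
  stop_if_not(all(x >= 0), "error counts must be non-negative")
  k <- 0:max(x)
  cum <- vapply(k, function(ki) 100 * mean(x >= ki), numeric(1))
  out <- data.frame(errors = k, cumulative_pct = cum)
  structure(out, class = c("cwit_error_table", "data.frame"),
            subtest = subtest, n_available = length(x),
            n_missing = sum(is.na(errors)))
}

#' Screen error counts for demographic and performance associations
#'
#' Spearman rank correlations of errors with age and education, a
#' Mann-Whitney test of the sex difference with the rank-biserial
#' correlation (`1 - 2U/(n1 n2)`; normal approximation, tie-corrected, no
#' continuity correction), and the Pearson correlation between errors and
#' the same subtest's completion time with its Fisher-z 95% CI.
#'
#' @param cohort cohort data.frame with error and time columns.
#' @param subtests error subtests to screen.
#' @return data.frame with one row per subtest.
#' @export
screen_associations <- function(cohort, subtests = cwit_error_subtests()) {
  one <- function(st) {
    err <- cohort[[paste0(st, "_errors")]]
    tim <- cohort[[paste0(st, "_time")]]
    ok <- !is.na(err)
    stop_if_not(sum(ok) >= 10, "need >= 10 complete cases")
    err <- err[ok]
    sp <- function(v) {
      if (stats::sd(v) == 0 || stats::sd(err) == 0) return(NA_real_)
      stats::cor(err, v, method = "spearman")
    }
    f <- cohort$sex[ok] == "female"
    n1 <- sum(f)
    n2 <- sum(!f)
    mw <- stats::wilcox.test(err[f], err[!f], exact = FALSE, correct = FALSE)
    U <- unname(mw$statistic)  # U for the female group
    ct <- stats::cor.test(err, tim[ok])
    data.frame(subtest = st,
               rho_age = sp(cohort$age[ok]),
               rho_edu = sp(cohort$education[ok]),
               u = U, mw_p = mw$p.value,
               rank_biserial = 1 - 2 * U / (n1 * n2),
               r_time = unname(ct$estimate),
               r_time_lo = ct$conf.int[1], r_time_hi = ct$conf.int[2],
               r_time_p = ct$p.value)
  }
  out <- do.call(rbind, lapply(subtests, one))
  rownames(out) <- NULL
  out
}

#' Compare completion times between extreme error groups
#'
#' Dichotomizes participants into those with zero errors on both error
#' subtests and those with at least `threshold` errors on either, then
#' compares completion time on each subtest with Welch two-sample t-tests
#' (no equal-variance assumption, Satterthwaite df).
#'
#' @param cohort cohort data.frame.
#' @param threshold error count defining the high-error group (default 4).
#' @return data.frame with group means/SDs/sizes, t, df, p and the mean
#'   difference per subtest.
#' @export
compare_extreme_groups <- function(cohort, threshold = 4) {
  e3 <- cohort$cwit3_errors
  e4 <- cohort$cwit4_errors
  complete <- !is.na(e3) & !is.na(e4)
  zero <- complete & e3 == 0 & e4 == 0
  high <- complete & (e3 >= threshold | e4 >= threshold)
  if (!any(high)) {
    stop("no participants reach ", threshold,
         " errors; threshold too extreme for this sample", call. = FALSE)
  }
  stop_if_not(any(zero), "no zero-error participants")
  one <- function(st) {
    tim <- cohort[[paste0(st, "_time")]]
    if (stats::sd(tim[zero], na.rm = TRUE) == 0 &&
        stats::sd(tim[high], na.rm = TRUE) == 0 &&
        mean(tim[zero], na.rm = TRUE) == mean(tim[high], na.rm = TRUE)) {
      # degenerate but well-defined: identical constant groups do not differ
      return(data.frame(subtest = st, n_zero = sum(zero & !is.na(tim)),
                        n_high = sum(high & !is.na(tim)),
                        mean_zero = mean(tim[zero], na.rm = TRUE),
                        sd_zero = 0, mean_high = mean(tim[high], na.rm = TRUE),
                        sd_high = 0, mean_diff = 0, t = 0, df = NA_real_,
                        p = 1))
    }
    tt <- stats::t.test(tim[zero], tim[high])
    data.frame(subtest = st, n_zero = sum(zero & !is.na(tim)),
               n_high = sum(high & !is.na(tim)),
               mean_zero = mean(tim[zero], na.rm = TRUE),
               sd_zero = stats::sd(tim[zero], na.rm = TRUE),
               mean_high = mean(tim[high], na.rm = TRUE),
               sd_high = stats::sd(tim[high], na.rm = TRUE),
               mean_diff = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  out <- do.call(rbind, lapply(cwit_error_subtests(), one))
  rownames(out) <- NULL
  out
}
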