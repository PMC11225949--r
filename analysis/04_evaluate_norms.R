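#!/usr/bin/env Rscript
# Stage 4: audit norm sets against the cohort.
#
# Scores the cohort with its generating (Norwegian) norms -- the correctly
# specified case -- and with an age-only norm set rebuilt from the cohort
# while ignoring sex and education, emulating the structure of the original
# age-adjusted external norms. The audit machinery should exonerate the
# former and flag the latter: maladjustment regressions on T-scores, paired
# t-tests between the two sets of T-scores, low-score (T < 35) base rates
# with 99% Wilson CIs, and McNemar tests of the paired low-score flags.

suppressPackageStartupMessages(library(cwitnorms))

cohort <- read_cohort("results/cohort_cross_sectional.csv")
nor <- norwegian_norms()
ctr <- c(age = 46.2, edu = 15.5)

# age-only norms: refit each subtest with age + age^2 only
age_only_eqs <- lapply(names(nor$equations), function(st) {
  s <- raw_to_scaled(nor$tables[[st]], cohort[[paste0(st, "_time")]])
  X <- design_matrix(cohort$age, cohort$education, cohort$sex,
                     c("age", "age2"), ctr)
  extract_equation(fit_ols(X, s), st, ctr)
})
names(age_only_eqs) <- names(nor$equations)
age_only <- normset("age-only", age_only_eqs, nor$tables)

score_wide <- function(ns) {
  sc <- score_batch(ns, cohort)
  out <- lapply(split(sc, sc$subtest), function(d) d$t[match(cohort$id, d$id)])
  as.data.frame(out)
}
t_full <- score_wide(nor)
t_age <- score_wide(age_only)

demo <- cohort[, c("age", "education", "sex")]
mal_full <- maladjustment_regression(t_full, demo)
mal_age <- maladjustment_regression(t_age, demo)
mal <- rbind(cbind(norms = "generating", mal_full),
             cbind(norms = "age-only", mal_age))
utils::write.csv(mal, "results/maladjustment.csv", row.names = FALSE)
flg <- subset(mal, flagged)
cat("maladjustment flags (predictor p < .05):\n")
if (nrow(flg)) print(flg[, c("norms", "subtest", "predictor", "b", "p")],
                     digits = 3) else cat("  none\n")

cmp <- do.call(rbind, lapply(names(t_full), function(st) {
  cbind(subtest = st, paired_norm_comparison(t_age[[st]], t_full[[st]]))
}))
utils::write.csv(cmp, "results/norm_comparison_paired_t.csv",
                 row.names = FALSE)
cat("\npaired t: age-only minus generating T-scores:\n")
print(cmp[, c("subtest", "mean_diff", "t", "p", "cohens_d")], digits = 3)

br <- do.call(rbind, lapply(names(t_full), function(st) {
  rbind(cbind(norms = "generating", subtest = st,
              base_rate_analysis(t_full[[st]])),
        cbind(norms = "age-only", subtest = st,
              base_rate_analysis(t_age[[st]])))
}))
utils::write.csv(br, "results/base_rates.csv", row.names = FALSE)
cat("\nlow-score (T < 35) base rates vs expected 6.7%:\n")
print(br[, c("norms", "subtest", "proportion_pct", "ci_lo_pct", "ci_hi_pct",
             "covers_expected")], digits = 3)

mcn <- do.call(rbind, lapply(names(t_full), function(st) {
  cbind(subtest = st,
        mcnemar_paired(t_age[[st]] < 35, t_full[[st]] < 35))
}))
utils::write.csv(mcn, "results/mcnemar_low_scores.csv", row.names = FALSE)
cat("\nMcNemar on paired low-score flags (age-only vs generating):\n")
print(mcn[, c("subtest", "b", "c", "chi_square", "p")], digits = 3)
cat("\nwrote results/maladjustment.csv, results/norm_comparison_paired_t.csv,",
    "results/base_rates.csv, results/mcnemar_low_scores.csv\n")
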