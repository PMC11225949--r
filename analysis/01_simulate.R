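#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Emulates the normative sample (n = 1011; age 20-85 with a thin middle-age
# band, education 7-23, two thirds female) with completion times generated
# from the published normative equations, error counts from the calibrated
# hurdle model, and a retest arm of 357 pairs of which ~22 fall beyond the
# 5-year interval limit and will be excluded downstream.

suppressPackageStartupMessages(library(cwitnorms))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

seed <- 20230901
spec <- simulation_spec(n = 1011, seed = seed)
cohort <- simulate_cohort(spec)
write_cohort(cohort, file.path(out_dir, "cohort_cross_sectional.csv"))

retest_spec <- simulation_spec(
  n = 357, seed = seed + 1,
  retest = list(target_icc = c(cwit1 = 0.68, cwit2 = 0.68, cwit3 = 0.76,
                               cwit4 = 0.70),
                practice = 0,
                interval = list(mean = 3.4, sd = 0.9, range = c(1, 5)),
                p_overlimit = 22 / 357))
base <- gen_cwit_times(gen_demographics(retest_spec), retest_spec$norms,
                       seed = seed + 2)
retest <- gen_retest(base, retest_spec, seed = seed + 3)
write_cohort(retest, file.path(out_dir, "cohort_longitudinal.csv"))

cat(sprintf("normative cohort: n = %d, mean age %.1f (SD %.1f), %.1f%% female, mean education %.1f\n",
            nrow(cohort), mean(cohort$age), sd(cohort$age),
            100 * mean(cohort$sex == "female"), mean(cohort$education)))
cat(sprintf("retest arm: n = %d pairs, %d with interval > 5 y\n",
            nrow(retest), sum(retest$interval_years > 5)))
cat("wrote", file.path(out_dir, "cohort_cross_sectional.csv"), "and",
    file.path(out_dir, "cohort_longitudinal.csv"), "\n")
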