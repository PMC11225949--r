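# Synthetic cohorts with the demographic and effect structure the normative
# analyses assume: a bimodal age distribution on [20, 85] (the normative
# sample under-represents the middle-aged), discretized truncated-normal
# education, Bernoulli sex, latent scaled scores generated from a normative
# equation plus residual noise and inverted through the conversion table to
# raw times, hurdle negative-binomial error counts, and correlated retest
# scores. All generators are deterministic given their seed.

#' Simulation specification
#'
#' Defaults reproduce the normative sample's reported marginals: n = 1011,
#' age mean 46.2 / SD 19.4 on \[20, 85\] (as a two-component truncated-normal
#' mixture centered near 30 and 68), education mean 15.5 / SD 2.9 on
#' \[7, 23\], 66.8% female, the packaged Norwegian norms as the generating
#' equations/tables, error models calibrated to the published cumulative
#' error percentages, and a retest arm with interval mean 3.4 y (SD 0.9) on
#' \[1, 5\].
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @param p_female probability of female sex.
#' @param age_model list: `means`, `sds` (component means/SDs), `weight`
#'   (probability of the first, younger component), `range`.
#' @param edu_model list: `mean`, `sd`, `range` (integerized truncated
#'   normal).
#' @param norms generating [normset()].
#' @param error_models named list per error subtest of hurdle-NB parameters
#'   `c(p_pos, size, mu)`; default calibrated via [fit_error_model()] to the
#'   packaged cumulative error percentages.
#' @param retest list: `target_icc` (named per subtest), `practice` (mean
#'   scaled-score change at follow-up), `interval` (`mean`, `sd`, `range`),
#'   `p_overlimit` (fraction of intervals drawn beyond the range maximum, to
#'   exercise interval filtering).
#' @return object of class `cwit_simspec`.
#' @export
simulation_spec <- function(n = 1011, seed = 1, p_female = 0.668,
                            age_model = list(means = c(30, 68),
                                             sds = c(6.006, 8.932),
                                             weight = 0.5766,
                                             range = c(20, 85)),
                            edu_model = list(mean = 15.5, sd = 2.9,
                                             range = c(7, 23)),
                            norms = norwegian_norms(),
                            error_models = default_error_models(),
                            retest = list(
                              target_icc = c(cwit1 = 0.68, cwit2 = 0.68,
                                             cwit3 = 0.76, cwit4 = 0.70),
                              practice = 0,
                              interval = list(mean = 3.4, sd = 0.9,
                                              range = c(1, 5)),
                              p_overlimit = 0)) {
  stop_if_not(n >= 1, "n must be >= 1")
  stop_if_not(p_female >= 0 && p_female <= 1, "p_female must be in [0, 1]")
  stop_if_not(all(age_model$sds > 0) && edu_model$sd > 0, "SDs must be positive")
  stop_if_not(all(retest$target_icc > 0 & retest$target_icc < 1),
              "target_icc must be in (0, 1)")
  structure(list(n = n, seed = seed, p_female = p_female,
                 age_model = age_model, edu_model = edu_model, norms = norms,
                 error_models = error_models, retest = retest),
            class = "cwit_simspec")
}

# rejection sampler for a truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate cohort demographics
#'
#' @param spec a [simulation_spec()].
#' @param seed overriding seed (defaults to `spec$seed`).
#' @return cohort data.frame (cross-sectional schema, times empty).
#' @export
gen_demographics <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n
  am <- spec$age_model
  comp <- 2L - stats::rbinom(n, 1, am$weight)  # 1 = younger component
  age <- numeric(n)
  for (k in 1:2) {
    idx <- comp == k
    if (any(idx)) {
      age[idx] <- rtruncnorm(sum(idx), am$means[k], am$sds[k],
                             am$range[1], am$range[2])
    }
  }
  em <- spec$edu_model
  edu <- round(rtruncnorm(n, em$mean, em$sd, em$range[1] - 0.499,
                          em$range[2] + 0.499))
  sex <- factor(ifelse(stats::runif(n) < spec$p_female, "female", "male"),
                levels = c("male", "female"))
  d <- data.frame(id = sprintf("S%05d", seq_len(n)), age = age,
                  education = as.integer(edu), sex = sex)
  for (col in setdiff(cohort_columns("cross_sectional"), names(d))) {
    d[[col]] <- NA_real_
  }
  attr(d, "schema") <- "cross_sectional"
  d
}

# map an integer latent scaled score to the nearest scaled value that has a
# bin in the table (some published tables skip scaled values); ties resolve
# toward the distribution center (10)
snap_to_table <- function(s, avail) {
  vapply(s, function(si) {
    d <- abs(avail - si)
    cand <- avail[d == min(d)]
    cand[which.min(abs(cand - 10))]
  }, numeric(1))
}

# draw an integer raw time uniformly within the bin for each scaled score;
# open-ended extreme bins get a geometric tail beyond the closed bound
draw_raw_in_bin <- function(table, s, tail_p = 0.25) {
  bins <- table$bins
  idx <- match(s, bins$scaled)
  lo <- bins$low[idx]
  hi <- bins$high[idx]
  raw <- numeric(length(s))
  open_lo <- is.infinite(lo)
  open_hi <- is.infinite(hi)
  closed <- !open_lo & !open_hi
  if (any(closed)) {
    raw[closed] <- lo[closed] +
      floor(stats::runif(sum(closed)) * (hi[closed] - lo[closed] + 1))
  }
  if (any(open_lo)) {  # best bin: at or below its upper bound
    raw[open_lo] <- pmax(1, hi[open_lo] - stats::rgeom(sum(open_lo), tail_p))
  }
  if (any(open_hi)) {  # worst bin: at or above its lower bound
    raw[open_hi] <- lo[open_hi] + stats::rgeom(sum(open_hi), tail_p)
  }
  raw
}

#' Generate CWIT completion times from a normset
#'
#' For each subtest with an equation, draws a latent scaled score
#' `y* = predicted + N(0, sd_residual)`, clips the rounded value to 1-19
#' (snapping to the nearest scaled value present in the conversion table),
#' and draws the raw time uniformly over the integer raw values of that
#' scaled score's bin (geometric tail in the open-ended extreme bins). By
#' construction `raw_to_scaled(raw)` returns the generating integer scaled
#' score for every record.
#'
#' @param cohort demographics from [gen_demographics()].
#' @param norms generating [normset()].
#' @param seed integer seed.
#' @return cohort with `cwit*_time` filled; the latent continuous and
#'   integer scaled scores are attached as `attr(, "latent")` (a data.frame
#'   keyed by id and subtest) for oracle tests.
#' @export
gen_cwit_times <- function(cohort, norms = norwegian_norms(), seed = 1) {
  set.seed(seed)
  lat <- list()
  for (st in names(norms$equations)) {
    eq <- norms$equations[[st]]
    tab <- norms$tables[[st]]
    mu <- predict_scaled(eq, cohort$age, cohort$education, cohort$sex)
    ystar <- mu + stats::rnorm(nrow(cohort), 0, eq$sd_residual)
    s <- pmin(pmax(round_half_away(ystar), 1), 19)
    s <- snap_to_table(s, available_scaled(tab))
    cohort[[paste0(st, "_time")]] <- draw_raw_in_bin(tab, s)
    lat[[st]] <- data.frame(id = cohort$id, subtest = st, predicted = mu,
                            latent = ystar, scaled = as.integer(s))
  }
  attr(cohort, "latent") <- do.call(rbind, c(lat, list(make.row.names = FALSE)))
  cohort
}

#' Fit a hurdle negative-binomial error model to cumulative percentages
#'
#' The hurdle model sets `P(errors >= 1)` directly to the observed value and
#' fits the NB `size` and `mu` of the positive part by least squares against
#' the cumulative percentages at `k = 2..kmax`.
#'
#' @param cumulative numeric vector of cumulative percentages indexed
#'   `k = 1, 2, ...` (percent of the sample with at least k errors).
#' @param kmax highest k used in the fit (default 6; the published tail
#'   beyond that is sparse).
#' @return named vector `c(p_pos, size, mu)`.
#' @export
fit_error_model <- function(cumulative, kmax = 6) {
  targ <- cumulative[seq_len(min(kmax, length(cumulative)))] / 100
  p1 <- targ[1]
  obj <- function(par) {
    s <- stats::pnbinom(seq_along(targ) - 1, size = exp(par[1]),
                        mu = exp(par[2]), lower.tail = FALSE)
    sum((p1 * s / s[1] - targ)^2)
  }
  o <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                    control = list(maxit = 10000, reltol = 1e-14))
  c(p_pos = p1, size = exp(o$par[1]), mu = exp(o$par[2]))
}

#' Default error models calibrated to the packaged error norms
#'
#' @return named list of [fit_error_model()] parameter vectors for
#'   `cwit3` and `cwit4`.
#' @export
default_error_models <- function() {
  tab <- norwegian_error_percentages()
  lapply(stats::setNames(nm = cwit_error_subtests()),
         function(st) fit_error_model(tab[[st]][tab$errors >= 1]))
}

# draw from the hurdle NB: zero with prob 1 - p_pos, else zero-truncated NB
rhurdle_nb <- function(n, par) {
  pos <- stats::runif(n) < par[["p_pos"]]
  out <- integer(n)
  if (any(pos)) {
    p0 <- stats::pnbinom(0, size = par[["size"]], mu = par[["mu"]])
    u <- p0 + stats::runif(sum(pos)) * (1 - p0)
    out[pos] <- stats::qnbinom(u, size = par[["size"]], mu = par[["mu"]])
  }
  out
}

#' Generate error counts
#'
#' Error counts are independent of demographics by construction, matching
#' the near-null associations observed in the normative sample.
#'
#' @param cohort cohort data.frame.
#' @param error_models per-subtest hurdle-NB parameters
#'   (default [default_error_models()]).
#' @param seed integer seed.
#' @return cohort with `cwit3_errors`, `cwit4_errors` filled.
#' @export
gen_errors <- function(cohort, error_models = default_error_models(),
                       seed = 1) {
  set.seed(seed)
  for (st in names(error_models)) {
    cohort[[paste0(st, "_errors")]] <- rhurdle_nb(nrow(cohort),
                                                  error_models[[st]])
  }
  cohort
}

#' Generate follow-up scores for a retest arm
#'
#' Follow-up latent scaled scores are drawn bivariate-normally around the
#' same demographic prediction: `y2* = mu + practice + r (y1* - mu) +
#' sqrt(1 - r^2) * sd_residual * e`. The latent correlation `r` is the
#' target ICC inflated by the integer-rounding attenuation factor
#' `(sd^2 + 1/12) / sd^2`, so the ICC computed on normed (T) scores of the
#' discretized records recovers the target. Intervals are truncated-normal
#' on the configured range; a fraction `p_overlimit` is drawn beyond the
#' maximum to exercise interval filtering.
#'
#' @param syncohort cohort from [gen_cwit_times()] (its `"latent"`
#'   attribute supplies the baseline latent scores).
#' @param spec a [simulation_spec()] (its `norms` and `retest` components
#'   are used).
#' @param seed integer seed.
#' @return longitudinal-schema cohort data.frame with `interval_years` and
#'   `cwit*_time_fu` columns.
#' @export
gen_retest <- function(syncohort, spec = simulation_spec(), seed = 1) {
  lat <- attr(syncohort, "latent")
  stop_if_not(!is.null(lat), "cohort lacks latent scores; run gen_cwit_times first")
  set.seed(seed)
  rt <- spec$retest
  norms <- spec$norms
  n <- nrow(syncohort)
  out <- syncohort
  for (st in names(norms$equations)) {
    eq <- norms$equations[[st]]
    tab <- norms$tables[[st]]
    li <- lat[lat$subtest == st, ]
    li <- li[match(syncohort$id, li$id), ]
    target <- rt$target_icc[[st]]
    stop_if_not(target > 0 && target < 1, "target_icc must be in (0, 1)")
    atten <- (eq$sd_residual^2 + 1 / 12) / eq$sd_residual^2
    r <- min(target * atten, 0.99999)
    y2 <- li$predicted + rt$practice + r * (li$latent - li$predicted) +
      sqrt(1 - r^2) * eq$sd_residual * stats::rnorm(n)
    s2 <- snap_to_table(pmin(pmax(round_half_away(y2), 1), 19),
                        available_scaled(tab))
    out[[paste0(st, "_time_fu")]] <- draw_raw_in_bin(tab, s2)
  }
  iv <- rt$interval
  interval <- rtruncnorm(n, iv$mean, iv$sd, iv$range[1], iv$range[2])
  if (rt$p_overlimit > 0) {
    over <- stats::runif(n) < rt$p_overlimit
    interval[over] <- iv$range[2] + stats::runif(sum(over), 0.1, 2)
  }
  out$interval_years <- interval
  attr(out, "schema") <- "longitudinal"
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: demographics, completion times and error counts in
#' one call, with sub-seeds derived deterministically from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return cohort data.frame with a `"latent"` attribute.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  d <- gen_demographics(spec)
  d <- gen_cwit_times(d, spec$norms, seed = spec$seed + 1e6)
  gen_errors(d, spec$error_models, seed = spec$seed + 2e6)
}
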