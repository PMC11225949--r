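#' Construct a normative equation
#'
#' A self-contained regression equation on the scaled-score metric: scoring
#' an individual requires only the intercept, term coefficients, centering
#' constants and residual SD.
#'
#' @param subtest subtest key.
#' @param intercept intercept in scaled-score units.
#' @param coefficients named numeric vector; names are term labels among
#'   `age, age2, age3, edu, edu2, edu3, female, age:female, edu:female,
#'   age:edu`. Age/education terms apply to mean-centered values.
#' @param centering named numeric vector `c(age = ..., edu = ...)` giving
#'   the centering means in years.
#' @param sd_residual residual standard deviation in scaled-score units.
#' @param stats optional data.frame of per-term statistics (se, t, p,
#'   partial_r2).
#' @param adj_r2 optional adjusted R-squared of the fit.
#' @param n optional normative sample size.
#' @return object of class `cwit_equation`.
#' @export
normative_equation <- function(subtest, intercept, coefficients,
                               centering = c(age = 46.2, edu = 15.5),
                               sd_residual, stats = NULL, adj_r2 = NA_real_,
                               n = NA_integer_) {
  stop_if_not(sd_residual > 0, "sd_residual must be positive")
  stop_if_not(all(names(coefficients) %in% all_terms()),
              "unknown term label in coefficients")
  stop_if_not(all(c("age", "edu") %in% names(centering)),
              "centering must name age and edu")
  structure(list(subtest = subtest, intercept = intercept,
                 coefficients = coefficients, centering = centering,
                 sd_residual = sd_residual, stats = stats,
                 adj_r2 = adj_r2, n = n),
            class = "cwit_equation")
}

#' @export
print.cwit_equation <- function(x, ...) {
  cat(sprintf("Normative equation [%s]: intercept %.3f, SD residual %.3f\n",
              x$subtest, x$intercept, x$sd_residual))
  if (length(x$coefficients)) {
    cat("  terms:", paste(sprintf("%s = %.4g", names(x$coefficients),
                                  x$coefficients), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bundle equations and conversion tables into a norm set
#'
#' @param label free-text label for the norms.
#' @param equations named list of [normative_equation()]s per subtest.
#' @param tables named list of [conversion_table()]s per subtest.
#' @param version version string for provenance.
#' @return object of class `cwit_normset`.
#' @export
normset <- function(label, equations, tables, version = "1.0") {
  stop_if_not(all(names(equations) %in% names(tables)),
              "every equation needs a matching conversion table")
  structure(list(label = label, equations = equations, tables = tables,
                 version = version),
            class = "cwit_normset")
}

#' @export
print.cwit_normset <- function(x, ...) {
  cat(sprintf("CWIT norm set '%s' (version %s): %s\n", x$label, x$version,
              paste(names(x$equations), collapse = ", ")))
  invisible(x)
}

#' Predicted scaled score from demographics
#'
#' Evaluates `intercept + sum(b_d * d)` over the equation's (centered)
#' demographic terms. A demographic outside the norms' stated range
#' (age 20-85) triggers a warning but scoring proceeds: the normative range
#' is advisory, not a hard bound.
#'
#' @param eq a [normative_equation()].
#' @param age age in years.
#' @param edu education in years.
#' @param sex anything [parse_sex()] accepts.
#' @return predicted scaled score(s), full precision.
#' @export
predict_scaled <- function(eq, age, edu, sex) {
  stop_if_not(inherits(eq, "cwit_equation"), "not a normative equation")
  if (any(age < 20 | age > 85, na.rm = TRUE)) {
    warning("age outside the normative range 20-85; prediction is an extrapolation")
  }
  X <- design_matrix(age, edu, sex, terms = names(eq$coefficients),
                     centering = eq$centering)
  drop(eq$intercept + X %*% eq$coefficients)
}

#' Score one raw completion time against a norm set
#'
#' The full normative chain: raw time -> obtained scaled score (conversion
#' table lookup) -> demographically predicted scaled score (equation) ->
#' `Z = (obtained - predicted) / SD_residual` -> `T = 10 Z + 50`. The
#' integer T report is rounded half away from zero from the unrounded T.
#'
#' @param norms a [normset()], e.g. [norwegian_norms()].
#' @param subtest subtest key.
#' @param raw raw completion time(s) in seconds.
#' @param age,edu,sex demographics (recycled against `raw`).
#' @return data.frame with columns `subtest, raw, obtained_scaled,
#'   predicted_scaled, z, t, t_rounded, percentile`.
#' @export
score_cwit <- function(norms, subtest, raw, age, edu, sex) {
  stop_if_not(inherits(norms, "cwit_normset"), "not a norm set")
  stop_if_not(subtest %in% names(norms$equations),
              "subtest not in norm set: ", subtest)
  eq <- norms$equations[[subtest]]
  tab <- norms$tables[[subtest]]
  obtained <- raw_to_scaled(tab, raw)
  predicted <- predict_scaled(eq, age, edu, sex)
  z <- (obtained - predicted) / eq$sd_residual
  t <- 10 * z + 50
  data.frame(subtest = subtest, raw = raw, obtained_scaled = obtained,
             predicted_scaled = predicted, z = z, t = t,
             t_rounded = as.integer(round_half_away(t)),
             percentile = 100 * stats::pnorm(z))
}

#' Score every available (person, subtest) pair in a cohort
#'
#' Missing raw times yield no row for that pair (never a zero score).
#'
#' @param norms a [normset()].
#' @param cohort a cohort data.frame in the cross-sectional schema
#'   (see [read_cohort()]).
#' @param time_cols optional named character vector mapping subtest keys to
#'   the cohort columns holding the raw times (defaults to
#'   `cwit*_time`); used to score follow-up columns of longitudinal data.
#' @return data.frame with `id`, demographics and the [score_cwit()] columns.
#' @export
score_batch <- function(norms, cohort, time_cols = NULL) {
  if (is.null(time_cols)) {
    time_cols <- paste0(cwit_subtests(), "_time")
    names(time_cols) <- cwit_subtests()
  }
  time_cols <- time_cols[names(time_cols) %in% names(norms$equations)]
  out <- lapply(names(time_cols), function(st) {
    col <- time_cols[[st]]
    if (!col %in% names(cohort)) return(NULL)
    ok <- !is.na(cohort[[col]])
    if (!any(ok)) return(NULL)
    cbind(data.frame(id = cohort$id[ok], age = cohort$age[ok],
                     education = cohort$education[ok],
                     sex = cohort$sex[ok]),
          score_cwit(norms, st, cohort[[col]][ok], cohort$age[ok],
                     cohort$education[ok], cohort$sex[ok]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(), age = numeric(), education = numeric(),
                      sex = character(), subtest = character(), raw = numeric(),
                      obtained_scaled = integer(), predicted_scaled = numeric(),
                      z = numeric(), t = numeric(), t_rounded = integer(),
                      percentile = numeric())
  }
  rownames(out) <- NULL
  out
}
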