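# Demographic regression models on CWIT scaled scores: the full candidate
# model is age + age^2 + age^3 + sex + education + education^2 + education^3
# + age*sex + education*sex + age*education, with age and education
# mean-centered; it is simplified stepwise under a marginality-respecting
# hierarchy and a nested-F criterion at alpha = .01.

#' Full set of candidate model terms
#' @return character vector of the ten candidate term labels.
#' @export
all_terms <- function() {
  c("age", "age2", "age3", "edu", "edu2", "edu3", "female",
    "age:female", "edu:female", "age:edu")
}

# terms that must stay in the model while `term` is present (marginality)
term_requires <- function(term) {
  switch(term,
    age2 = "age", age3 = c("age", "age2"),
    edu2 = "edu", edu3 = c("edu", "edu2"),
    `age:female` = c("age", "female"),
    `edu:female` = c("edu", "female"),
    `age:edu` = c("age", "edu"),
    character(0))
}

# drop-priority tier: interactions before cubics before quadratics before mains
term_tier <- function(term) {
  ifelse(grepl(":", term), 4L,
         ifelse(grepl("3$", term), 3L, ifelse(grepl("2$", term), 2L, 1L)))
}

#' Build the centered demographic design matrix
#'
#' Age and education enter as deviations from the centering means (and their
#' powers); `female` is the 0/1 indicator; interactions are products of the
#' centered components.
#'
#' @param age,edu,sex demographic vectors.
#' @param terms character vector of term labels (subset of [all_terms()]).
#' @param centering named vector `c(age = ..., edu = ...)`.
#' @return numeric matrix with one named column per term.
#' @export
design_matrix <- function(age, edu, sex, terms = all_terms(),
                          centering = c(age = 46.2, edu = 15.5)) {
  stop_if_not(all(terms %in% all_terms()), "unknown term label")
  stop_if_not(!anyNA(age) && !anyNA(edu), "missing demographic values")
  a <- age - centering[["age"]]
  e <- edu - centering[["edu"]]
  f <- sex_to_female(sex)
  stop_if_not(!anyNA(f), "missing or unparseable sex values")
  cols <- list(age = a, age2 = a^2, age3 = a^3, edu = e, edu2 = e^2,
               edu3 = e^3, female = f, `age:female` = a * f,
               `edu:female` = e * f, `age:edu` = a * e)
  n <- max(length(a), length(e), length(f))
  X <- vapply(cols[terms], function(v) rep_len(v, n), numeric(n))
  if (is.null(dim(X))) X <- matrix(X, nrow = n, dimnames = list(NULL, terms))
  X
}

#' Ordinary least squares fit with per-term normative statistics
#'
#' Wraps [stats::lm()] and augments it with the quantities the normative
#' tables report: residual SD (`sqrt(SSE / df_residual)`), per-term partial
#' R-squared (`t^2 / (t^2 + df_residual)`), adjusted R-squared, BIC and the
#' coefficient covariance matrix.
#'
#' @param X design matrix from [design_matrix()] (no intercept column).
#' @param y response vector (scaled scores).
#' @return object of class `cwit_ols`: a list with `lm`, `coefficients`
#'   (data.frame of b, se, t, p, partial_r2 incl. the intercept),
#'   `sd_residual`, `adj_r2`, `r2`, `bic`, `df_residual`, `vcov`, `n`.
#' @export
fit_ols <- function(X, y) {
  stop_if_not(nrow(X) >= ncol(X) + 2, "too few rows for the number of terms")
  dat <- data.frame(y = y, X, check.names = FALSE)
  fml <- if (ncol(X) == 0) y ~ 1 else
    stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < ncol(X) + 1) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; offending columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  dfres <- fit$df.residual
  coefs <- data.frame(
    term = gsub("`", "", rownames(ct)), b = ct[, 1], se = ct[, 2],
    t = ct[, 3], p = ct[, 4],
    partial_r2 = ct[, 3]^2 / (ct[, 3]^2 + dfres), row.names = NULL)
  coefs$term[coefs$term == "(Intercept)"] <- "intercept"
  structure(list(lm = fit, coefficients = coefs,
                 sd_residual = sqrt(sum(stats::residuals(fit)^2) / dfres),
                 adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
                 bic = stats::BIC(fit), df_residual = dfres,
                 vcov = stats::vcov(fit), n = length(y)),
            class = "cwit_ols")
}

#' @export
print.cwit_ols <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, adj R2 = %.3f, SD residual = %.3f\n",
              x$n, x$adj_r2, x$sd_residual))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Hierarchy-respecting stepwise model simplification
#'
#' Starting from the full candidate model, repeatedly drops one term:
#' candidates are terms whose higher-order dependents are already gone
#' (marginality), ordered interactions first, then cubics, quadratics,
#' mains, and within a tier by largest current p-value. A drop is accepted
#' iff the nested-model F comparison gives `p >= alpha` (simplification
#' preferred at equality); BIC is recorded at every step but never overrides
#' the F criterion. Selection stops when no candidate drop is acceptable.
#'
#' @param cohort cohort data.frame with `age`, `education`, `sex` and a
#'   scaled-score response column.
#' @param response name of the response column (integer scaled scores), or a
#'   numeric vector.
#' @param terms starting term set (default [all_terms()]).
#' @param alpha significance criterion for *retaining* a term (default .01).
#' @param centering centering means; defaults to the cohort means of age and
#'   education (freeze at published constants when rebuilding published
#'   equations).
#' @return list with `fit` (the final [fit_ols()] object), `terms`, `trace`
#'   (data.frame of candidate drops with F, p, BIC before/after, decision)
#'   and `centering`.
#' @export
select_model <- function(cohort, response, terms = all_terms(), alpha = 0.01,
                         centering = NULL) {
  y <- if (is.character(response)) cohort[[response]] else response
  if (is.null(centering)) {
    centering <- c(age = mean(cohort$age), edu = mean(cohort$education))
  }
  ok <- !is.na(y)
  cohort <- cohort[ok, , drop = FALSE]
  y <- y[ok]
  current <- terms
  fit <- fit_ols(design_matrix(cohort$age, cohort$education, cohort$sex,
                               current, centering), y)
  trace <- list()
  repeat {
    needed <- unique(unlist(lapply(current, term_requires)))
    droppable <- setdiff(current, needed)
    if (length(droppable) == 0) break
    pvals <- fit$coefficients$p[match(droppable, fit$coefficients$term)]
    ord <- order(-term_tier(droppable), -pvals)
    accepted <- FALSE
    for (cand in droppable[ord]) {
      reduced_terms <- setdiff(current, cand)
      reduced <- fit_ols(design_matrix(cohort$age, cohort$education,
                                       cohort$sex, reduced_terms, centering), y)
      cmp <- stats::anova(reduced$lm, fit$lm)
      Fstat <- cmp$F[2]
      p <- cmp$`Pr(>F)`[2]
      keep_drop <- p >= alpha
      trace[[length(trace) + 1]] <- data.frame(
        term = cand, F = Fstat, p = p, bic_before = fit$bic,
        bic_after = reduced$bic,
        decision = if (keep_drop) "dropped" else "retained")
      if (keep_drop) {
        current <- reduced_terms
        fit <- reduced
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(term = character(), F = numeric(), p = numeric(),
               bic_before = numeric(), bic_after = numeric(),
               decision = character())
  list(fit = fit, terms = current, trace = trace, centering = centering)
}

#' Extract a self-contained normative equation from a fit
#'
#' @param fit a [fit_ols()] object.
#' @param subtest subtest key.
#' @param centering the centering means the design used.
#' @return a [normative_equation()].
#' @export
extract_equation <- function(fit, subtest, centering) {
  stop_if_not(inherits(fit, "cwit_ols"), "not a cwit_ols fit")
  cf <- fit$coefficients
  terms <- setdiff(cf$term, "intercept")
  b <- cf$b[match(terms, cf$term)]
  names(b) <- terms
  normative_equation(
    subtest = subtest, intercept = cf$b[cf$term == "intercept"],
    coefficients = b, centering = centering, sd_residual = fit$sd_residual,
    stats = cf, adj_r2 = fit$adj_r2, n = fit$n)
}

#' Residual and influence diagnostics for a normative fit
#'
#' Standardized residuals, Cook's distances and a heteroscedasticity
#' descriptive (correlation between absolute residuals and fitted values).
#' Observations are never deleted automatically.
#'
#' @param fit a [fit_ols()] object.
#' @return list with `residuals` (data.frame: fitted, residual,
#'   std_residual, cooks_d) and `het_cor`.
#' @export
ols_diagnostics <- function(fit) {
  stop_if_not(inherits(fit, "cwit_ols"), "not a cwit_ols fit")
  res <- stats::residuals(fit$lm)
  perfect <- sum(res^2) < 1e-12
  std <- if (perfect) rep(0, length(res)) else stats::rstandard(fit$lm)
  cd <- if (perfect) rep(0, length(res)) else stats::cooks.distance(fit$lm)
  het <- if (perfect || stats::sd(abs(res)) == 0) NA_real_ else
    stats::cor(abs(res), stats::fitted(fit$lm))
  list(residuals = data.frame(fitted = stats::fitted(fit$lm), residual = res,
                              std_residual = std, cooks_d = cd),
       het_cor = het)
}

#' Seemingly unrelated regressions for two subtests
#'
#' Estimates the two normative equations jointly by one-step feasible GLS
#' with an unrestricted cross-equation residual covariance, so that
#' cross-equation coefficient contrasts have covariance-adjusted standard
#' errors.
#'
#' @param cohort cohort data.frame (complete cases on both responses are
#'   used).
#' @param responseA,responseB response column names (scaled scores).
#' @param termsA,termsB term sets of the two equations.
#' @param centering centering means (cohort means by default).
#' @return list with per-equation coefficient vectors `b1`, `b2`, the joint
#'   covariance `vcov`, term name bookkeeping and `n`.
#' @export
fit_sur <- function(cohort, responseA, responseB, termsA, termsB,
                    centering = NULL) {
  ok <- !is.na(cohort[[responseA]]) & !is.na(cohort[[responseB]])
  cohort <- cohort[ok, , drop = FALSE]
  if (is.null(centering)) {
    centering <- c(age = mean(cohort$age), edu = mean(cohort$education))
  }
  y1 <- cohort[[responseA]]
  y2 <- cohort[[responseB]]
  X1 <- cbind(intercept = 1, design_matrix(cohort$age, cohort$education,
                                           cohort$sex, termsA, centering))
  X2 <- cbind(intercept = 1, design_matrix(cohort$age, cohort$education,
                                           cohort$sex, termsB, centering))
  n <- length(y1)
  # per-equation OLS for the residual covariance (one-step FGLS)
  b1o <- solve(crossprod(X1), crossprod(X1, y1))
  b2o <- solve(crossprod(X2), crossprod(X2, y2))
  e1 <- y1 - X1 %*% b1o
  e2 <- y2 - X2 %*% b2o
  S <- matrix(c(sum(e1 * e1), sum(e1 * e2), sum(e1 * e2), sum(e2 * e2)),
              2, 2) / n
  # bound |residual correlation| away from 1 so the weighting stays invertible
  # (degenerate only when the two responses are identical)
  rmax <- 1 - 1e-9
  r12 <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (abs(r12) > rmax) {
    S[1, 2] <- S[2, 1] <- sign(r12) * rmax * sqrt(S[1, 1] * S[2, 2])
  }
  W <- solve(S)
  k1 <- ncol(X1); k2 <- ncol(X2)
  # normal equations of the stacked GLS system, Omega^{-1} = W (x) I_n
  A <- rbind(cbind(W[1, 1] * crossprod(X1), W[1, 2] * crossprod(X1, X2)),
             cbind(W[2, 1] * crossprod(X2, X1), W[2, 2] * crossprod(X2)))
  rhs <- c(W[1, 1] * crossprod(X1, y1) + W[1, 2] * crossprod(X1, y2),
           W[2, 1] * crossprod(X2, y1) + W[2, 2] * crossprod(X2, y2))
  V <- solve(A)
  b <- drop(V %*% rhs)
  nm <- c(paste0("eq1_", colnames(X1)), paste0("eq2_", colnames(X2)))
  names(b) <- nm
  dimnames(V) <- list(nm, nm)
  list(b1 = b[seq_len(k1)], b2 = b[k1 + seq_len(k2)], vcov = V,
       terms1 = colnames(X1), terms2 = colnames(X2), n = n, sigma = S)
}

#' Z-test for equality of a coefficient across two subtests
#'
#' Fits the two equations as seemingly unrelated regressions on the same
#' participants and tests `b1 - b2 = 0` with the covariance-adjusted
#' standard error `sqrt(var(b1) + var(b2) - 2 cov(b1, b2))`.
#'
#' @inheritParams fit_sur
#' @param term the coefficient to compare (present in both equations).
#' @return data.frame with `term, b1, b2, diff, se_diff, z, p`.
#' @export
test_equality <- function(cohort, responseA, responseB, termsA, termsB,
                          term = "age", centering = NULL) {
  stop_if_not(term %in% termsA && term %in% termsB,
              "term must be present in both equations: ", term)
  sur <- fit_sur(cohort, responseA, responseB, termsA, termsB, centering)
  n1 <- paste0("eq1_", term)
  n2 <- paste0("eq2_", term)
  d <- sur$b1[[n1]] - sur$b2[[n2]]
  se <- sqrt(max(sur$vcov[n1, n1] + sur$vcov[n2, n2] - 2 * sur$vcov[n1, n2], 0))
  z <- if (abs(d) < 1e-10 || se == 0) 0 else d / se
  data.frame(term = term, b1 = sur$b1[[n1]], b2 = sur$b2[[n2]], diff = d,
             se_diff = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
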