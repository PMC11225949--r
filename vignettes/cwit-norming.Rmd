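---
title: "Regression-based norming of the Color-Word Interference Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based norming of the Color-Word Interference Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwitnorms)
```

## The problem

The Color-Word Interference Test (CWIT) is the Stroop variant of the
Delis-Kaplan Executive Function System. Its four subtests — color naming
(CWIT-1), word reading (CWIT-2), inhibition (CWIT-3) and
inhibition/switching (CWIT-4) — each time the completion of 50 items in
seconds. Raw completion times are strongly related to age (non-linearly),
and more weakly to education and sex, so a raw time is clinically
meaningful only relative to what is *expected* for a person of that age,
education and sex. `cwitnorms` implements the regression-based
(continuous) norming approach for these subtests: rather than stratifying
a normative sample into demographic cells, it models expected performance
as a smooth function of demographics and standardizes the residual.

The package ships the published Norwegian normative material for adults
aged 20–85 (n = 1011) as `norwegian_norms()`, and implements every stage
needed to *rebuild* such norms from a cohort, to *audit* an external norm
set against a cohort, and to quantify *stability* of normed scores over
time.

## The model

### Raw times to scaled scores

Because completion-time distributions are right-skewed, raw times are
first normalized by percentile rank. For a raw value $v$ with $f$ ties and
$c$ strictly slower observations in a sample of size $N$, the performance
percentile is the midpoint rank

$$p(v) = 100\,\frac{c + f/2}{N},$$

oriented so faster times score higher. Percentiles map to integer scaled
scores with mean 10 and SD 3 via the normal quantile function,

$$s = \mathrm{clip}\big(\mathrm{round}(10 + 3\,\Phi^{-1}(p/100)),\,1,\,19\big),$$

with rounding half away from zero — the convention that reproduces all 19
published percentile anchors (50 → 10, 84 → 13, 99 → 17, 0.4 → 2, …).
Consecutive raw values sharing a scaled score are merged into the bins of
a conversion table whose extreme bins are open-ended; published tables are
shipped as data and never re-derived at scoring time. Raw times are
treated as integer seconds, matching the published bin bounds.

The exact percentile convention behind the published tables is not
documented; the midpoint-rank rule used here is the classical-test-theory
convention and is validated against every printed anchor and bin lookup we
can check.

### The normative regression

Scaled scores are regressed on demographics. The full candidate model is

$$s = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3 + \beta_4 e +
\beta_5 e^2 + \beta_6 e^3 + \beta_7 F + \beta_8 aF + \beta_9 eF +
\beta_{10} ae + \varepsilon,$$

where $a$ is age centered at its mean, $e$ education centered at its mean,
and $F$ the female indicator (0 = male, 1 = female). Centering is frozen
at the published constants (46.2 and 15.5 years) when scoring with the
packaged equations, and computed from the data when building new norms;
both paths are explicit in the API.

The model is simplified stepwise under a marginality-respecting hierarchy:
candidate drops are terms whose higher-order dependents are already gone,
tried interactions first, then cubics, quadratics, mains, and within a
tier in order of largest current p-value. A drop is accepted iff the
nested-model F comparison yields $p \ge .01$, i.e. simplification is
preferred at exact equality — the natural resolution of a boundary that
could be read either way. BIC is recorded at every step for reporting but
never overrides the F criterion. Exact intermediate comparison sets of any
particular historical run are unknowable; only the endpoint structure is
verifiable, which is what the package's recovery tests target.

### Scoring

For an individual with raw time $r$, the obtained scaled score
$s_{obt}$ comes from the conversion table, the predicted scaled score
$s_{pred}$ from the equation, and

$$Z = \frac{s_{obt} - s_{pred}}{SD_{resid}}, \qquad T = 10\,Z + 50.$$

The reporting chain mirrors the published worked example: predicted score
and Z are displayed to 2 decimals, the integer T is rounded half away from
zero from the *unrounded* T (45.93 → 46), and full precision is carried
internally throughout. A companion published example for an 80-year-old is
reproducible only to ±2 T with the printed coefficients, because the
3-decimal rounding of the age² coefficient is amplified at a centered age
of 33.8 years; the package treats that case as a tolerance check rather
than an exact target. Demographics outside 20–85 years warn but still
score: the range is advisory for a clinical calculator.

### Coefficient equality across subtests

Whether age affects, say, inhibition more than word reading is a question
about the *difference* of two coefficients estimated on the same people.
The package fits the two equations jointly as seemingly unrelated
regressions (one-step feasible GLS with an unrestricted cross-equation
residual covariance — iterated FGLS would also be defensible; one-step is
the common default and is what the equality z-test needs) and tests
$b_1 - b_2 = 0$ with the covariance-adjusted standard error. With
identical regressor sets SUR collapses to per-equation OLS, an identity
the tests exploit as an oracle.

### Error counts

Errors on CWIT-3/4 are zero-heavy and over-dispersed and associate only
weakly with demographics, so they are normed as unstratified cumulative
percentages, $C(k) = 100\,\Pr(\text{errors} \ge k)$. The association
screen (Spearman, Mann-Whitney with rank-biserial effect size, Pearson
against completion time) and a Welch comparison of zero-error vs
$\ge 4$-error groups support that choice on any cohort. The Mann-Whitney
test uses the tie-corrected normal approximation without continuity
correction, appropriate at normative sample sizes. Error recording covers
only CWIT-3/4; the basic subtests are unsupported by design.

### Auditing a norm set

If norms adjust correctly, T-scores are unrelated to demographics, average
50, and place about $\Phi(-1.5) = 6.7\%$ of a healthy sample below
T < 35. The audit module regresses T-scores on age, education and sex
(flagging predictors at $\alpha = .05$), compares two norm sets by paired
t-tests, tests observed low-score rates against 6.7% with an uncorrected
one-proportion z-test and a 99% Wilson score CI, and compares paired
low-score flags with the asymptotic McNemar test without continuity
correction, $(b-c)^2/(b+c)$. Wilson's interval is used because it behaves
well at small proportions; the construction is isolated in `wilson_ci()`
so a different interval can be substituted in one place. A low score is
strictly $T < 35$.

### Stability and reliable change

Retest pairs with intervals beyond 5 years are excluded before analysis.
Stability is the intraclass correlation of the single-rating,
absolute-agreement, two-way model,

$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the F-distribution confidence interval of McGraw & Wong — the
standard CI for this form. ICCs are computed on demographically adjusted
T-scores by default (a raw scaled-score option exists), since stability of
*normed* scores is the clinically relevant quantity. Conventional bands
label .5–.75 moderate and .75–.9 good. Reliable change indices come in the
three canonical forms (Jacobson-Truax, practice-adjusted,
regression-based); `stability_report()` emits the means, SDs, retest
correlation and mean practice effect a user needs to apply them.

## The synthetic-cohort generator

The original normative cohort is available only on request, so validation
runs on synthetic cohorts that reproduce its structure:

* **Demographics.** Age is a two-component truncated-normal mixture on
  [20, 85] centered near 30 and 68 (weight 0.577 on the younger
  component, SDs 6.01 and 8.93), reproducing the reported mean 46.2, SD
  19.4 and the thin middle-age band; the published text gives no
  parametric form, so the mixture is an artifact convention. Education is
  a rounded truncated normal on [7, 23] (mean 15.5, SD 2.9); sex is
  Bernoulli(.668).
* **Completion times.** A latent scaled score
  $y^* = s_{pred} + N(0, SD_{resid})$ is drawn from a generating
  equation, rounded and clipped to 1–19 (snapping to the nearest scaled
  value present in the table where a published table skips values, ties
  toward 10), and the raw time is drawn uniformly over the integer raw
  values of that score's bin — a geometric tail (p = .25) beyond the
  open-ended extreme bins. Inverting the published table rather than
  fitting a parametric time distribution guarantees exact raw↔scaled
  consistency, which is what downstream tests need; the within-bin
  distribution is likewise an artifact convention.
* **Errors.** A hurdle negative binomial per subtest: the probability of
  any error is matched exactly to the published cumulative percentage at
  k = 1, and the zero-truncated NB size/mu are least-squares fitted to
  k ≤ 6. A zero-*inflated* NB was evaluated first and rejected: the
  published marginals are zero-*deflated* relative to the NB, driving the
  inflation mass to the zero boundary and leaving calibration errors near
  1 percentage point, while the hurdle form fits to ≤ 0.2. Parameters are
  refit from the packaged table at generation time by
  `fit_error_model()`. Errors are independent of demographics *and* of
  completion time by construction — the near-null demographic
  associations mirror the normative sample; the error–time coupling seen
  in real data is not emulated and is injected explicitly where a test
  needs it.
* **Retest.** Follow-up latent scores are bivariate-normal around the
  same prediction with latent correlation equal to the target ICC
  inflated by the rounding attenuation $(SD_{resid}^2 + 1/12)/SD_{resid}^2$,
  so the ICC measured on discretized normed scores recovers the target.
  Intervals are truncated-normal (mean 3.4 y, SD 0.9) on [1, 5], with an
  optional fraction beyond 5 to exercise the exclusion filter.

What passing tests on such cohorts shows is that the *pipeline* is
correct — percentile machinery inverts, coefficients and ICCs are
recovered, audits flag planted misadjustments; it does not certify the
published coefficient values themselves, which only the restricted cohort
could, and it does not probe robustness to features the generator omits
(measurement non-normality beyond discretization, attrition, error–time
coupling, practice heterogeneity).

## Numerical choices and degenerate inputs

* Rounding half away from zero everywhere a published rounding is
  implied; R's default banker's rounding would disagree at .5 boundaries.
* Percentile ranks require ≥ 2 distinct values; table building requires
  ≥ 50 observations to stabilize the tails.
* OLS is `stats::lm()`; rank deficiency is an error naming the collinear
  columns. Partial $R^2 = t^2/(t^2 + df_{resid})$ uses the residual df of
  the final model.
* The SUR residual correlation is bounded away from ±1 (at $1-10^{-9}$)
  so the GLS weighting stays invertible; the bound binds only when the
  two responses are identical, where the equality z is defined as 0.
* The ICC is degenerate without between-subject variance (error); perfect
  agreement reports a [1, 1] interval.
* McNemar with no discordant pairs reports p = 1 with an explanatory
  note. Welch comparison of two identical constant groups reports t = 0.
* Missing values: missing raw times or error counts propagate as absent
  results, never zeros; a missing error count is distinct from zero
  errors throughout the I/O layer.

## Validation problem sizes

The test suite validates marginal calibration at n = 100,000 (error and
self-consistency checks), coefficient recovery at n = 10,000 over 100
seeds (each coefficient within ±2 SE of its generating value in ≥ 90% of
seeds — the per-coefficient criterion; a joint all-coefficients criterion
would be miscalibrated by construction at ≈ .95^p per seed), selection
endpoint recovery at n = 5,000 over 100 seeds, and ICC coverage at the
retest arm's n = 335 over 100 seeds. Self-scored cohorts show mean T ≈ 50
and SD ≈ 10 within ±0.3 and low-score rates within about 0.6 pp of 6.7% —
the residual discretization bias of integer scaled scores, visible in the
published norms' own low-score rates (8.6%/8.3% on two subtests), which is
why the low-score self-consistency band is ±1 pp and the 99%-CI coverage
property carries a documented ±0.6 pp discretization allowance.

## Known limitations

* The stepwise search's intermediate states are a convention; only the
  endpoint is validated.
* The packaged CWIT-2 age² coefficient is printed in the source tables
  only as "<−0.001" and is transcribed as −0.001.
* Norms and audits assume cognitively healthy adults aged 20–85;
  extrapolation warns but is not blocked.
* Contrast scores between subtests and error norms for CWIT-1/2 are out
  of scope, as are GAM smooth-term alternatives, which were evaluated and
  rejected in the source analyses.
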