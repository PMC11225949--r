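# Published Norwegian CWIT norms: raw-to-scaled conversion tables, normative
# regression equations (scaled-score metric, age/education mean-centered at
# 46.2 / 15.5 years, sex coded 0 = male, 1 = female), and cumulative error
# percentages. Transcribed verbatim from the published norm tables; never
# re-derived at scoring time.

# percentile anchors shared by all four conversion tables (scaled 1..19)
.norwegian_anchors <- c(
  `1` = 0.1, `2` = 0.4, `3` = 1, `4` = 2, `5` = 5, `6` = 9, `7` = 16,
  `8` = 25, `9` = 37, `10` = 50, `11` = 63, `12` = 75, `13` = 84, `14` = 91,
  `15` = 95, `16` = 98, `17` = 99, `18` = 99.6, `19` = 99.9
)

.norwegian_bins <- function(subtest) {
  # rows: scaled, low, high (raw seconds); -Inf/Inf mark the open extremes
  m <- switch(subtest,
    cwit1 = rbind(
      c(19, -Inf, 18), c(18, 19, 19), c(17, 20, 20), c(16, 21, 21),
      c(15, 22, 22), c(14, 23, 24), c(13, 25, 25), c(12, 26, 26),
      c(11, 27, 28), c(10, 29, 30), c(9, 31, 32), c(8, 33, 34),
      c(7, 35, 36), c(6, 37, 39), c(5, 40, 41), c(4, 42, 45),
      c(3, 46, 47), c(2, 48, 55), c(1, 56, Inf)),
    cwit2 = rbind(
      c(18, -Inf, 14), c(16, 15, 15), c(15, 16, 16), c(14, 17, 17),
      c(13, 18, 18), c(12, 19, 19), c(11, 20, 20), c(10, 21, 22),
      c(9, 23, 23), c(8, 24, 24), c(7, 25, 26), c(6, 27, 27),
      c(5, 28, 30), c(4, 31, 33), c(3, 34, 36), c(2, 37, 51),
      c(1, 52, Inf)),
    cwit3 = rbind(
      c(19, -Inf, 26), c(18, 27, 30), c(17, 31, 32), c(16, 33, 34),
      c(15, 35, 36), c(14, 37, 39), c(13, 40, 41), c(12, 42, 44),
      c(11, 45, 48), c(10, 49, 52), c(9, 53, 57), c(8, 58, 62),
      c(7, 63, 68), c(6, 69, 76), c(5, 77, 84), c(4, 85, 98),
      c(3, 99, 113), c(2, 114, 129), c(1, 130, Inf)),
    cwit4 = rbind(
      c(19, -Inf, 30), c(18, 31, 33), c(17, 34, 36), c(16, 37, 38),
      c(15, 39, 41), c(14, 42, 44), c(13, 45, 47), c(12, 48, 50),
      c(11, 51, 54), c(10, 55, 59), c(9, 60, 64), c(8, 65, 70),
      c(7, 71, 77), c(6, 78, 87), c(5, 88, 100), c(4, 101, 116),
      c(3, 117, 132), c(2, 133, 167), c(1, 168, Inf)),
    stop("unknown subtest: ", subtest)
  )
  data.frame(low = m[, 2], high = m[, 3], scaled = as.integer(m[, 1]))
}

.norwegian_equations <- function() {
  list(
    cwit1 = normative_equation(
      subtest = "cwit1", intercept = 9.863,
      coefficients = c(age = -0.049, age2 = -0.001, female = 0.825),
      sd_residual = 2.775, adj_r2 = 0.155, n = 1011),
    cwit2 = normative_equation(
      subtest = "cwit2", intercept = 10.217,
      coefficients = c(age = -0.019, age2 = -0.001),
      sd_residual = 2.797, adj_r2 = 0.031, n = 1011),
    cwit3 = normative_equation(
      subtest = "cwit3", intercept = 10.182,
      coefficients = c(age = -0.073, age2 = -0.001, edu = 0.078, female = 0.454),
      sd_residual = 2.546, adj_r2 = 0.291, n = 1011),
    cwit4 = normative_equation(
      subtest = "cwit4", intercept = 10.561,
      coefficients = c(age = -0.063, age2 = -0.002, edu = 0.098),
      sd_residual = 2.574, adj_r2 = 0.250, n = 1011)
  )
}

#' The packaged Norwegian CWIT norms
#'
#' The published Norwegian normative material for adults aged 20-85
#' (n = 1011): per-subtest raw-to-scaled conversion tables with percentile
#' anchors, and the normative regression equations on the scaled-score
#' metric (mean-centered age and education; sex coded 0 = male, 1 = female).
#'
#' @return a [normset()] labelled `"norwegian-2023"`.
#' @export
norwegian_norms <- function() {
  tables <- lapply(cwit_subtests(), function(st) {
    anchors <- .norwegian_anchors[as.character(sort(unique(.norwegian_bins(st)$scaled)))]
    conversion_table(st, .norwegian_bins(st), anchors)
  })
  names(tables) <- cwit_subtests()
  normset(label = "norwegian-2023", equations = .norwegian_equations(),
          tables = tables, version = "1.0")
}

#' Published cumulative error percentages for CWIT-3 and CWIT-4
#'
#' Percentage of the normative sample (n = 936 with error data) making at
#' least `k` total (corrected + uncorrected) errors. `NA` marks error counts
#' not attained by any participant.
#'
#' @return data.frame with columns `errors`, `cwit3`, `cwit4`.
#' @export
norwegian_error_percentages <- function() {
  data.frame(
    errors = 0:11,
    cwit3 = c(100, 51.4, 23.2, 11.1, 5.2, 2.8, 1.2, 0.5, 0.4, 0.2, NA, 0.1),
    cwit4 = c(100, 55.4, 26.5, 12.9, 6.3, 3.2, 1.5, 1.1, 0.6, NA, NA, 0.2)
  )
}
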