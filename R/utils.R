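#' Round half away from zero
#'
#' Commercial rounding used throughout the scoring chain (45.5 becomes 46,
#' -45.5 becomes -46), as opposed to the IEC 60559 banker's rounding of
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# subtest keys used everywhere; CWIT-1 color naming, CWIT-2 word reading,
# CWIT-3 inhibition, CWIT-4 inhibition/switching
cwit_subtests <- function() c("cwit1", "cwit2", "cwit3", "cwit4")

# subtests with recorded error counts
cwit_error_subtests <- function() c("cwit3", "cwit4")

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

#' Parse heterogeneous sex codings
#'
#' Accepts `male`/`female`, `m`/`f` and `0`/`1` (0 = male, 1 = female),
#' case-insensitively, and returns a factor with levels `male`, `female`.
#' Unrecognized values become `NA` with a warning.
#'
#' @param x character, numeric or factor vector.
#' @return factor with levels `c("male", "female")`.
#' @export
parse_sex <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(v))
  out[v %in% c("male", "m", "0")] <- "male"
  out[v %in% c("female", "f", "1")] <- "female"
  bad <- !is.na(v) & v != "" & is.na(out)
  if (any(bad)) {
    warning("unrecognized sex codes: ", paste(unique(v[bad]), collapse = ", "))
  }
  factor(out, levels = c("male", "female"))
}

# numeric indicator used in all design matrices: 0 = male, 1 = female
sex_to_female <- function(sex) as.numeric(parse_sex(sex) == "female")
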