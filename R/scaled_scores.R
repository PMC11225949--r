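#' Performance percentile ranks for completion times
#'
#' Midpoint percentile ranks oriented so that *faster* completion (a lower
#' time) receives a *higher* percentile: for a raw value with `f` ties and
#' `c` observations strictly slower, the percentile is `100 * (c + f/2) / N`.
#' This is the classical-test-theory percentile-rank convention.
#'
#' @param raw_times numeric vector of completion times in seconds.
#' @return named numeric vector mapping each distinct raw value (names) to
#'   its performance percentile in (0, 100), ordered by increasing raw time.
#' @export
performance_percentiles <- function(raw_times) {
  x <- raw_times[!is.na(raw_times)]
  stop_if_not(length(unique(x)) >= 2,
              "need at least 2 distinct raw values; got a degenerate distribution")
  n <- length(x)
  vals <- sort(unique(x))
  freq <- tabulate(match(x, vals))
  slower <- rev(cumsum(rev(freq))) - freq  # strictly slower than each value
  p <- 100 * (slower + freq / 2) / n
  names(p) <- vals
  p
}

#' Map a percentile to an integer scaled score
#'
#' Scaled scores follow a normal distribution with mean 10 and SD 3:
#' `clip(round(10 + 3 * qnorm(p/100)), 1, 19)`, rounding half away from zero.
#'
#' @param p percentile(s) in the open interval (0, 100).
#' @return integer scaled score(s) in 1..19.
#' @export
percentile_to_scaled <- function(p) {
  stop_if_not(all(p > 0 & p < 100), "percentile must be strictly between 0 and 100")
  s <- round_half_away(10 + 3 * stats::qnorm(p / 100))
  as.integer(pmin(pmax(s, 1), 19))
}

#' Construct a conversion table object
#'
#' @param subtest subtest key, e.g. `"cwit1"`.
#' @param bins data.frame with integer columns `low`, `high` (use `-Inf` /
#'   `Inf` for the open-ended extreme bins) and `scaled`; bins must be
#'   contiguous over integer raw times and scaled must strictly decrease as
#'   raw time increases.
#' @param anchors optional named numeric vector mapping scaled scores to
#'   their percentile anchor.
#' @return object of class `cwit_conversion_table`.
#' @export
conversion_table <- function(subtest, bins, anchors = NULL) {
  stop_if_not(all(c("low", "high", "scaled") %in% names(bins)),
              "bins must have columns low, high, scaled")
  bins <- bins[order(bins$low), , drop = FALSE]
  rownames(bins) <- NULL
  stop_if_not(all(bins$low <= bins$high), "each bin needs low <= high")
  stop_if_not(all(bins$scaled >= 1 & bins$scaled <= 19), "scaled scores must lie in 1..19")
  if (nrow(bins) > 1) {
    stop_if_not(all(diff(bins$scaled) < 0),
                "scaled must strictly decrease with raw time")
    stop_if_not(all(bins$low[-1] == bins$high[-nrow(bins)] + 1),
                "bins must be contiguous over integer raw times")
  }
  stop_if_not(is.infinite(bins$low[1]) && is.infinite(bins$high[nrow(bins)]),
              "extreme bins must be open-ended")
  structure(list(subtest = subtest, bins = bins, anchors = anchors),
            class = "cwit_conversion_table")
}

#' @export
print.cwit_conversion_table <- function(x, ...) {
  cat("Raw-to-scaled conversion table:", x$subtest,
      sprintf("(%d bins, scaled %d-%d)\n", nrow(x$bins),
              min(x$bins$scaled), max(x$bins$scaled)))
  invisible(x)
}

#' Build a raw-to-scaled conversion table from a normative sample
#'
#' Each observed raw value is assigned `percentile_to_scaled()` of its
#' performance percentile; consecutive raw values sharing a scaled score are
#' merged into bins, and the extreme bins are opened to +/- infinity.
#' Percentile anchors are recorded as `100 * pnorm((s - 10) / 3)` for each
#' scaled score present.
#'
#' @param raw_times numeric vector of completion times (>= 50 observations).
#' @param subtest subtest key.
#' @return a [conversion_table()] object.
#' @export
build_conversion_table <- function(raw_times, subtest) {
  x <- raw_times[!is.na(raw_times)]
  stop_if_not(length(x) >= 50,
              "need >= 50 observations to build a stable conversion table")
  p <- performance_percentiles(x)
  vals <- as.numeric(names(p))
  scl <- percentile_to_scaled(p)
  # merge runs of equal scaled score into bins over increasing raw time
  runs <- rle(scl)
  hi_idx <- cumsum(runs$lengths)
  lo_idx <- hi_idx - runs$lengths + 1
  bins <- data.frame(low = vals[lo_idx], high = vals[hi_idx], scaled = runs$values)
  # close gaps between observed raw values so the table covers all integers
  if (nrow(bins) > 1) bins$high[-nrow(bins)] <- bins$low[-1] - 1
  bins$low[1] <- -Inf
  bins$high[nrow(bins)] <- Inf
  anchors <- 100 * stats::pnorm((sort(unique(scl)) - 10) / 3)
  names(anchors) <- sort(unique(scl))
  conversion_table(subtest, bins, anchors)
}

#' Look up the scaled score for a raw completion time
#'
#' @param table a [conversion_table()] object.
#' @param raw numeric vector of raw completion times in seconds (> 0).
#' @return integer scaled scores.
#' @export
raw_to_scaled <- function(table, raw) {
  stop_if_not(inherits(table, "cwit_conversion_table"), "not a conversion table")
  stop_if_not(all(raw > 0, na.rm = TRUE), "raw times must be positive")
  bins <- table$bins
  idx <- findInterval(raw, bins$low)  # last bin whose low <= raw
  out <- as.integer(bins$scaled[idx])
  out[is.na(raw)] <- NA_integer_
  out
}

# scaled scores that have a bin in the table
available_scaled <- function(table) sort(unique(table$bins$scaled))
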