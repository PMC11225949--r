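# Cohort CSV schemas. Cross-sectional columns: id, age, education, sex,
# cwit1_time..cwit4_time, cwit3_errors, cwit4_errors, mmse. The longitudinal
# schema appends interval_years and cwit*_time_fu follow-up columns.
# Missing optional cells are empty strings (never sentinel numbers): a
# missing error count is distinct from zero errors.

cohort_columns <- function(schema = c("cross_sectional", "longitudinal")) {
  schema <- match.arg(schema)
  base <- c("id", "age", "education", "sex",
            paste0(cwit_subtests(), "_time"),
            paste0(cwit_error_subtests(), "_errors"), "mmse")
  if (schema == "longitudinal") {
    base <- c(base, "interval_years", paste0(cwit_subtests(), "_time_fu"))
  }
  base
}

#' Read a cohort CSV
#'
#' Validates every row against the schema invariants; offending rows are
#' dropped with row-indexed messages (collected into one warning and
#' attached as the `"rejected"` attribute). Empty cells in optional columns
#' become `NA`.
#'
#' Row invariants: education in \[0, 30\]; times positive; error counts
#' non-negative; parseable sex; and, when `norm_building = TRUE`, age within
#' the normative inclusion range 20-85.
#'
#' @param path CSV file path (comma-separated, header row, `.` decimal).
#' @param schema `"cross_sectional"` or `"longitudinal"`.
#' @param norm_building enforce the age 20-85 inclusion criterion.
#' @return validated cohort data.frame; rejected row messages in
#'   `attr(, "rejected")`.
#' @export
read_cohort <- function(path, schema = c("cross_sectional", "longitudinal"),
                        norm_building = FALSE) {
  schema <- match.arg(schema)
  stop_if_not(file.exists(path), "no such file: ", path)
  cols <- cohort_columns(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), cols)) {
    stop("header does not match the ", schema, " schema; expected: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_cohort(schema))
  num <- function(col, what) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(v != "" & is.na(out))
    if (length(bad)) {
      stop(sprintf("row %d: non-numeric %s value '%s'", bad[1], what,
                   v[bad[1]]), call. = FALSE)
    }
    out
  }
  d <- data.frame(id = trimws(raw$id), age = num("age", "age"),
                  education = num("education", "education"),
                  sex = suppressWarnings(parse_sex(raw$sex)),
                  stringsAsFactors = FALSE)
  for (col in setdiff(cols, c("id", "age", "education", "sex"))) {
    d[[col]] <- num(col, col)
  }
  msgs <- character(0)
  bad <- rep(FALSE, nrow(d))
  flag <- function(cond, msg) {
    idx <- which(cond & !is.na(cond))
    bad[idx] <<- TRUE
    msgs <<- c(msgs, sprintf("row %d: %s", idx, msg))
  }
  flag(is.na(d$id) | d$id == "", "missing id")
  flag(is.na(d$age), "missing age")
  flag(is.na(d$sex), "missing or unparseable sex")
  flag(d$education < 0 | d$education > 30, "education outside [0, 30]")
  if (norm_building) flag(d$age < 20 | d$age > 85, "age outside inclusion range 20-85")
  for (col in grep("_time", cols, value = TRUE)) {
    flag(d[[col]] <= 0, paste(col, "not positive"))
  }
  for (col in grep("_errors", cols, value = TRUE)) {
    flag(d[[col]] < 0, paste(col, "negative"))
  }
  if (schema == "longitudinal") flag(d$interval_years <= 0, "interval_years not positive")
  keep <- d[!bad, , drop = FALSE]
  if (anyDuplicated(keep$id)) {
    stop("duplicate ids: ", paste(unique(keep$id[duplicated(keep$id)]),
                                  collapse = ", "), call. = FALSE)
  }
  rownames(keep) <- NULL
  if (length(msgs)) {
    warning(length(msgs), " row(s) rejected:\n",
            paste(msgs, collapse = "\n"))
  }
  attr(keep, "rejected") <- msgs
  attr(keep, "schema") <- schema
  keep
}

empty_cohort <- function(schema) {
  cols <- cohort_columns(schema)
  d <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  d$id <- character(0)
  d$sex <- factor(character(0), levels = c("male", "female"))
  attr(d, "schema") <- schema
  d
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: fixed column order, `NA` as empty cells,
#' UTF-8, `.` decimal. Round-trips field-for-field including missingness.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @param schema CSV schema to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         schema = c("cross_sectional", "longitudinal")) {
  schema <- if (!is.null(attr(cohort, "schema"))) attr(cohort, "schema")
            else match.arg(schema)
  cols <- cohort_columns(schema)
  out <- cohort
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out <- out[, cols, drop = FALSE]
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(out, utf8, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# -- normset serialization ---------------------------------------------------

#' Serialize a norm set to JSON
#'
#' Equations keep their intercept, coefficients, centering constants and
#' residual SD; conversion-table open bin bounds (-Inf/Inf) are encoded as
#' nulls. The file carries the normset label and an explicit version.
#'
#' @param norms a [normset()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_normset <- function(norms, path) {
  stop_if_not(inherits(norms, "cwit_normset"), "not a norm set")
  enc_eq <- function(eq) {
    list(subtest = eq$subtest, intercept = eq$intercept,
         coefficients = as.list(eq$coefficients),
         centering = as.list(eq$centering), sd_residual = eq$sd_residual,
         adj_r2 = eq$adj_r2, n = eq$n)
  }
  enc_tab <- function(tb) {
    bins <- tb$bins
    list(subtest = tb$subtest,
         bins = lapply(seq_len(nrow(bins)), function(i) list(
           low = if (is.infinite(bins$low[i])) NULL else bins$low[i],
           high = if (is.infinite(bins$high[i])) NULL else bins$high[i],
           scaled = bins$scaled[i])),
         anchors = if (is.null(tb$anchors)) NULL else as.list(tb$anchors))
  }
  obj <- list(label = norms$label, version = norms$version,
              equations = lapply(norms$equations, enc_eq),
              tables = lapply(norms$tables, enc_tab))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a norm set from JSON
#'
#' @param path a file written by [write_normset()].
#' @return a [normset()].
#' @export
read_normset <- function(path) {
  obj <- jsonlite::read_json(path)
  eqs <- lapply(obj$equations, function(e) {
    normative_equation(
      subtest = e$subtest, intercept = e$intercept,
      coefficients = unlist(e$coefficients),
      centering = unlist(e$centering), sd_residual = e$sd_residual,
      adj_r2 = if (is.null(e$adj_r2)) NA_real_ else e$adj_r2,
      n = if (is.null(e$n)) NA_integer_ else e$n)
  })
  tabs <- lapply(obj$tables, function(tb) {
    bins <- do.call(rbind, lapply(tb$bins, function(b) data.frame(
      low = if (is.null(b$low)) -Inf else b$low,
      high = if (is.null(b$high)) Inf else b$high,
      scaled = as.integer(b$scaled))))
    anchors <- if (is.null(tb$anchors)) NULL else unlist(tb$anchors)
    conversion_table(tb$subtest, bins, anchors)
  })
  normset(label = obj$label, equations = eqs, tables = tabs,
          version = obj$version)
}
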