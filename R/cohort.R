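#' @importFrom stats complete.cases pnorm qnorm runif rbinom setNames var
#' @importFrom utils read.csv write.csv
NULL

# Canonical cohort columns.  `age` is the baseline (entry) age; follow-up runs
# on the age timescale from `age` to `exit_age`.
.cohort_required <- c("sex", "age", "exit_age")
.cohort_optional <- c("id", "smoking", "sbp", "glucose", "cholesterol",
                      "diabetes", "fasting_hours", "event", "cause_code",
                      "icd_revision")
.cohort_numeric <- c("age", "exit_age", "sbp", "glucose", "cholesterol",
                     "fasting_hours")

#' Construct a validated cohort table
#'
#' A cohort table is a plain `data.frame` (class `cohort_table`) with one row
#' per subject and canonical columns: `id`, `sex` (`"male"`/`"female"`),
#' `age` (baseline age in years, the entry age on the age timescale),
#' `smoking` (current smoker, logical), `sbp` (systolic blood pressure, mmHg),
#' `glucose` and `cholesterol` (mmol/L), `diabetes` (logical),
#' `fasting_hours` (hours since last meal), `exit_age` (age at death or
#' censoring), `event` (death from cardiovascular disease, logical), and
#' optionally `cause_code` / `icd_revision` (ICD cause-of-death coding).
#'
#' Row-level invariants are enforced: baseline age at least 16 (the study
#' inclusion threshold), strictly positive blood pressure and blood markers
#' where present, `exit_age > age`, and consistency between `event` and an
#' ICD cause code when both are supplied.  Offending rows are dropped and
#' reported in the `"rejected"` attribute.
#'
#' @param data data.frame with (a subset of) the canonical columns.
#' @param provenance free-text label recording where the table came from.
#' @return A `cohort_table`; attribute `"rejected"` holds a data.frame of
#'   dropped rows (`row`, `reason`), attribute `"provenance"` the label.
#' @export
cohort_table <- function(data, provenance = "unspecified") {
  stopifnot(is.data.frame(data))
  missing_req <- setdiff(.cohort_required, names(data))
  if (length(missing_req))
    stopf("cohort is missing required column(s): %s",
          paste(missing_req, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  for (col in setdiff(c(.cohort_required, .cohort_optional), names(data)))
    data[[col]] <- NA
  data <- data[, c(.cohort_required[1:2], "exit_age",
                   setdiff(.cohort_optional, "id"), "id")]
  data <- data[, c("id", "sex", "age", "smoking", "sbp", "glucose",
                   "cholesterol", "diabetes", "fasting_hours", "exit_age",
                   "event", "cause_code", "icd_revision")]

  if (all(is.na(data$id))) data$id <- seq_len(nrow(data))
  if (anyDuplicated(stats::na.omit(data$id)))
    stopf("duplicate subject identifiers in cohort")

  data$sex <- .parse_sex(data$sex)
  for (col in .cohort_numeric) data[[col]] <- .as_num(data[[col]], col)
  for (col in c("smoking", "diabetes", "event"))
    data[[col]] <- .as_bool(data[[col]], col)
  data$cause_code <- as.character(data$cause_code)
  data$icd_revision <- .as_num(data$icd_revision, "icd_revision")

  # derive event status from ICD cause codes where available
  has_code <- !is.na(data$cause_code) & nzchar(data$cause_code) &
    !is.na(data$icd_revision)
  if (any(has_code)) {
    coded <- rep(NA, nrow(data))
    coded[has_code] <- classify_cvd_death(data$cause_code[has_code],
                                          data$icd_revision[has_code])
    if (all(is.na(data$event))) data$event[has_code] <- coded[has_code]
  } else {
    coded <- rep(NA, nrow(data))
  }
  data$event[is.na(data$event)] <- FALSE

  reasons <- character(nrow(data))
  bad <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond & !nzchar(reasons)] <<- why
  }
  bad(is.na(data$sex), "sex not male/female")
  bad(is.na(data$age), "unparseable or missing baseline age")
  bad(is.na(data$exit_age), "unparseable or missing exit age")
  bad(data$age < 16, "baseline age below 16")
  bad(data$exit_age <= data$age, "exit age not greater than entry age")
  for (col in c("sbp", "glucose", "cholesterol"))
    bad(data[[col]] <= 0, paste0("non-positive ", col))
  bad(data$fasting_hours < 0, "negative fasting_hours")
  bad(data$event & !is.na(coded) & !coded,
      "event marked CVD but cause code is non-circulatory")
  bad(!data$event & !is.na(coded) & coded,
      "cause code is circulatory but event not marked")

  keep <- !nzchar(reasons)
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            provenance = provenance,
            rejected = rejected,
            class = c("cohort_table", "data.frame"))
}

.parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("m", "male", "1")] <- "male"
  x[x %in% c("f", "female", "2")] <- "female"
  x[!x %in% c("male", "female")] <- NA_character_
  factor(x, levels = c("male", "female"))
}

.as_num <- function(x, col) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(as.numeric(as.character(x)))
}

.as_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a cohort CSV
#'
#' Reads a comma-separated cohort file (header row required, UTF-8, decimal
#' point) and validates it into a [cohort_table()].  Non-canonical column
#' names are resolved through `schema`, a named character vector (or a YAML
#' file containing one) mapping canonical names to the file's column names,
#' e.g. `c(sbp = "sys_bp")`.
#'
#' @param path CSV file path.
#' @param schema named character vector or YAML file path; `NULL` if the file
#'   already uses canonical names.
#' @param delim field delimiter, default comma.
#' @return A `cohort_table`; rejected rows are reported via the `"rejected"`
#'   attribute and a message.
#' @export
read_cohort <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema) &&
      grepl("\\.ya?ml$", schema))
    schema <- unlist(yaml::read_yaml(schema))
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src))
      stopf("schema maps to column(s) absent from %s: %s", path,
            paste(missing_src, collapse = ", "))
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  missing_req <- setdiff(.cohort_required, names(raw))
  if (length(missing_req))
    stopf("%s lacks required column(s): %s", path,
          paste(missing_req, collapse = ", "))
  tab <- cohort_table(raw, provenance = path)
  rej <- attr(tab, "rejected")
  message(sprintf("read_cohort: %d rows read, %d accepted, %d rejected",
                  nrow(raw), nrow(tab), nrow(rej)))
  tab
}

#' Write a cohort table to CSV
#'
#' Canonical comma-separated export; logical columns are written as
#' `TRUE`/`FALSE` so that a read/write cycle is lossless for finite-decimal
#' values.
#'
#' @param table a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify a cause-of-death ICD code as fatal CVD
#'
#' Fatal cardiovascular disease is defined by the circulatory-system chapters:
#' ICD-8 codes 390-458 and ICD-10 codes I00-I99.  Codes with subdivisions
#' (`"410.1"`, `"I21.9"`) are classified on their 3-character stem.
#' Revision 9 codes are rejected explicitly rather than guessed, as are codes
#' whose syntax does not match the revision.
#'
#' @param code character vector of ICD codes.
#' @param revision integer vector (8 or 10), recycled against `code`.
#' @return logical vector: `TRUE` for circulatory causes.
#' @export
classify_cvd_death <- function(code, revision) {
  code <- as.character(code)
  revision <- as.integer(revision)
  n <- max(length(code), length(revision))
  code <- rep_len(code, n)
  revision <- rep_len(revision, n)
  if (any(is.na(code) | !nzchar(trimws(code))))
    stopf("empty ICD code cannot be classified")
  if (any(!revision %in% c(8L, 10L)))
    stopf("unsupported ICD revision(s): %s (only 8 and 10 are defined)",
          paste(unique(revision[!revision %in% c(8L, 10L)]), collapse = ", "))
  code <- toupper(trimws(code))
  stem <- sub("[.].*$", "", code)
  out <- logical(n)
  i8 <- revision == 8L
  if (any(i8)) {
    ok <- grepl("^[0-9]{3}$", stem[i8])
    if (any(!ok))
      stopf("unrecognized ICD-8 code syntax: %s",
            paste(unique(code[i8][!ok]), collapse = ", "))
    num <- as.integer(stem[i8])
    out[i8] <- num >= 390L & num <= 458L
  }
  i10 <- revision == 10L
  if (any(i10)) {
    ok <- grepl("^[A-Z][0-9]{2}$", stem[i10])
    if (any(!ok))
      stopf("unrecognized ICD-10 code syntax: %s",
            paste(unique(code[i10][!ok]), collapse = ", "))
    out[i10] <- grepl("^I[0-9]{2}$", stem[i10])
  }
  out
}

#' Restrict a cohort to fasting subjects
#'
#' Drops subjects whose time since last meal is `min_hours` or less; subjects
#' with unknown fasting time are dropped as well (conservative reading of the
#' fasting inclusion rule).  The default reproduces the two-hour rule; four
#' hours is the usual sensitivity setting.
#'
#' @param table a `cohort_table`.
#' @param min_hours minimum fasting time in hours (exclusive bound).
#' @return Filtered `cohort_table`; number of removals is reported.
#' @export
fasting_filter <- function(table, min_hours = 2) {
  stopifnot(inherits(table, "cohort_table"), min_hours > 0)
  keep <- !is.na(table$fasting_hours) & table$fasting_hours > min_hours
  message(sprintf("fasting_filter: removed %d of %d records (fasting <= %g h or unknown)",
                  sum(!keep), nrow(table), min_hours))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop records with missing covariate values
#'
#' Listwise-complete restriction on the named covariates, mirroring the
#' complete-case analysis used before model fitting.
#'
#' @param table a `cohort_table`.
#' @param covariates character vector of canonical column names.
#' @return Filtered `cohort_table`.
#' @export
exclude_missing <- function(table, covariates) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(covariates, names(table))
  if (length(unknown))
    stopf("unknown covariate(s): %s", paste(unknown, collapse = ", "))
  if (!length(covariates)) return(table)
  keep <- complete.cases(as.data.frame(table)[, covariates, drop = FALSE])
  message(sprintf("exclude_missing: removed %d of %d records missing {%s}",
                  sum(!keep), nrow(table), paste(covariates, collapse = ", ")))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sex baseline summary of a cohort
#'
#' @param object a `cohort_table`.
#' @param ... unused.
#' @return data.frame with one row per sex: `n`, `events`, mean age, smoking
#'   proportion, mean SBP, glucose and cholesterol.  Empty strata are flagged
#'   with a warning and `NA` summaries.
#' @export
summary.cohort_table <- function(object, ...) {
  if (!nrow(object)) stopf("cannot summarize an empty cohort")
  out <- do.call(rbind, lapply(levels(object$sex), function(s) {
    sub <- object[object$sex %in% s, , drop = FALSE]
    if (!nrow(sub)) {
      warning(sprintf("empty stratum: %s", s), call. = FALSE)
      return(data.frame(sex = s, n = 0L, events = 0L, mean_age = NA_real_,
                        smoking = NA_real_, mean_sbp = NA_real_,
                        mean_glucose = NA_real_, mean_cholesterol = NA_real_))
    }
    data.frame(sex = s, n = nrow(sub), events = sum(sub$event),
               mean_age = mean(sub$age, na.rm = TRUE),
               smoking = mean(sub$smoking, na.rm = TRUE),
               mean_sbp = mean(sub$sbp, na.rm = TRUE),
               mean_glucose = mean(sub$glucose, na.rm = TRUE),
               mean_cholesterol = mean(sub$cholesterol, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d subjects (%d CVD deaths), provenance: %s\n",
              nrow(x), sum(x$event, na.rm = TRUE),
              attr(x, "provenance") %||% "unspecified"))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}
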