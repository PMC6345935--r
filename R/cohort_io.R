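#' Long-format clinical tables
#'
#' The universal input of the package is a long-format table of clinical
#' records in which each row is the measurement of a single feature for a
#' single subject at a particular time point: columns `subject_id`,
#' `feature_name`, `value` and `delta_days` (integer days relative to the
#' onset of clinical records).  Values are stored verbatim as text and
#' coerced to numbers per the feature dictionary at use time, because
#' clinical exports mix numeric and categorical features in one column.
#'
#' @param records a data frame with columns `subject_id`, `feature_name`,
#'   `value`, `delta_days`.
#' @return an object of class `clinical_table` (a data frame).
#' @examples
#' tab <- clinical_table(data.frame(
#'   subject_id = c("s1", "s1"), feature_name = "ALSFRS_Total",
#'   value = c("40", "31"), delta_days = c(92L, 365L)))
#' nrow(tab)
#' @export
clinical_table <- function(records) {
  needed <- c("subject_id", "feature_name", "value", "delta_days")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[needed]
  records$subject_id <- as.character(records$subject_id)
  records$feature_name <- as.character(records$feature_name)
  records$value <- as.character(records$value)
  dd <- suppressWarnings(as.numeric(records$delta_days))
  bad <- which(is.na(dd) | dd != round(dd))
  if (length(bad))
    stop("non-integer delta_days at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  records$delta_days <- as.integer(round(dd))
  if (any(!nzchar(records$subject_id)) || any(is.na(records$subject_id)))
    stop("empty subject_id")
  if (any(!nzchar(records$feature_name)) || any(is.na(records$feature_name)))
    stop("empty feature_name")
  rownames(records) <- NULL
  class(records) <- c("clinical_table", "data.frame")
  records
}

#' Feature dictionaries
#'
#' A feature dictionary declares every feature name as `continuous` or
#' `discrete` (with optional units) and is used to validate clinical
#' tables: a continuous feature must parse as a number in every record.
#'
#' @param feature_name character vector of feature names.
#' @param kind character vector, `"continuous"` or `"discrete"`.
#' @param units optional character vector of free-text units.
#' @return an object of class `feature_dictionary` (a data frame).
#' @export
feature_dictionary <- function(feature_name, kind, units = "") {
  kind <- match.arg(kind, c("continuous", "discrete"), several.ok = TRUE)
  d <- data.frame(feature_name = as.character(feature_name),
                  kind = rep_len(kind, length(feature_name)),
                  units = rep_len(as.character(units), length(feature_name)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$feature_name))
    stop("duplicated feature_name in dictionary")
  class(d) <- c("feature_dictionary", "data.frame")
  d
}

#' @rdname feature_dictionary
#' @param path path to a CSV file with header `feature_name,kind,units`.
#' @export
read_feature_dictionary <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  if (!all(c("feature_name", "kind") %in% names(d)))
    stop("dictionary file must have columns feature_name, kind")
  feature_dictionary(d$feature_name, d$kind, d$units %||% "")
}

#' Read and write long-format clinical tables
#'
#' Tables are comma-separated UTF-8 text with the header
#' `subject_id,feature_name,value,delta_days`.  When a dictionary is
#' supplied, every feature appearing in the table must have an entry and
#' continuous features must parse as numbers; violations raise an error
#' naming the offending line.
#'
#' @param path path to a CSV file.
#' @param dictionary optional [feature_dictionary()] used for validation.
#' @return [read_clinical_table()] returns a `clinical_table`;
#'   [write_clinical_table()] returns `path` invisibly.
#' @export
read_clinical_table <- function(path, dictionary = NULL) {
  raw <- tryCatch(utils::read.csv(path, colClasses = "character"),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  needed <- c("subject_id", "feature_name", "value", "delta_days")
  if (!all(needed %in% names(raw)))
    stop(path, ": header must contain ", paste(needed, collapse = ","))
  dd <- suppressWarnings(as.numeric(raw$delta_days))
  bad <- which(is.na(dd) | dd != round(dd))
  if (length(bad))  # +1 for the header line
    stop(path, ": malformed delta_days on line ", bad[1L] + 1L)
  tab <- clinical_table(raw)
  if (!is.null(dictionary)) validate_clinical_table(tab, dictionary)
  tab
}

#' @rdname read_clinical_table
#' @param table a `clinical_table`.
#' @export
write_clinical_table <- function(table, path) {
  stopifnot(inherits(table, "clinical_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_clinical_table
#' @export
validate_clinical_table <- function(table, dictionary) {
  stopifnot(inherits(dictionary, "feature_dictionary"))
  feats <- unique(table$feature_name)
  unknown <- setdiff(feats, dictionary$feature_name)
  if (length(unknown))
    stop("feature(s) missing from dictionary: ",
         paste(unknown, collapse = ", "))
  cont <- dictionary$feature_name[dictionary$kind == "continuous"]
  sel <- table$feature_name %in% cont
  bad <- sel & !is_number(table$value)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-numeric value ", shQuote(table$value[i]),
         " for continuous feature ", shQuote(table$feature_name[i]),
         " (row ", i, ")")
  }
  invisible(table)
}

#' Time windows over clinical records
#'
#' The challenge design splits the first year of records into two disjoint
#' windows: the observation window of the first three months (days 0-91
#' inclusive) from which predictions are made, and the outcome window
#' (days 92-365 inclusive) over which progression and survival ground
#' truth are defined.  Negative `delta_days` (pre-baseline screening) fall
#' outside both.
#'
#' @param start_day,end_day inclusive integer day bounds, `start_day <=
#'   end_day`.
#' @return an object of class `time_window`.
#' @examples
#' observation_window()  # days 0-91
#' outcome_window()      # days 92-365
#' @export
time_window <- function(start_day, end_day) {
  start_day <- as.integer(start_day); end_day <- as.integer(end_day)
  if (is.na(start_day) || is.na(end_day) || start_day > end_day)
    stop("invalid time window: need start_day <= end_day")
  structure(list(start_day = start_day, end_day = end_day),
            class = "time_window")
}

#' @rdname time_window
#' @export
observation_window <- function() time_window(0L, 91L)

#' @rdname time_window
#' @export
outcome_window <- function() time_window(92L, 365L)

#' Extract in-window records for one subject and feature
#'
#' Returns all records of `feature` for `subject` with `delta_days` inside
#' the closed window, sorted by `delta_days` ascending with ties kept in
#' input order.  An empty result is valid.
#'
#' @param table a `clinical_table`.
#' @param w a [time_window()].
#' @param subject subject identifier.
#' @param feature feature name.
#' @return a data frame with columns `delta_days` and `value`.
#' @export
window_records <- function(table, w, subject, feature) {
  stopifnot(inherits(w, "time_window"))
  sel <- table$subject_id == subject & table$feature_name == feature &
    table$delta_days >= w$start_day & table$delta_days <= w$end_day
  out <- data.frame(delta_days = table$delta_days[sel],
                    value = table$value[sel], stringsAsFactors = FALSE)
  out[order(out$delta_days), , drop = FALSE]
}

# Numeric view of record values; errors mention the feature for context.
numeric_values <- function(values, feature = NULL) {
  v <- suppressWarnings(as.numeric(values))
  if (anyNA(v) && !all(is.na(values)))
    stop("non-numeric value for feature ", shQuote(feature %||% "?"))
  v
}
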