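#' ALSFRS progression slope
#'
#' Disease progression ground truth is the slope of the total ALSFRS (or
#' ALSFRS-R) score between the first and last in-window records:
#' \deqn{slope = \frac{ALSFRS(t_2) - ALSFRS(t_1)}{t_2 - t_1}}
#' with times converted from days to months as `t_months = t_days/365 * 12`,
#' so the slope is in ALSFRS points per month.  The default window is the
#' outcome period, days 92-365 inclusive.  A subject needs at least two
#' in-window records; otherwise the slope is undefined and `NA` is
#' returned.  When several records share the first or last day their mean
#' value is used; if all in-window records fall on a single day with
#' conflicting values the input is degenerate and an error is raised.
#'
#' @param table a [clinical_table()].
#' @param subject subject identifier.
#' @param frs_feature name of the total-score feature (continuous).
#' @param window a [time_window()]; defaults to [outcome_window()].
#' @return slope in points/month, or `NA_real_` if the subject has fewer
#'   than two in-window records.
#' @examples
#' tab <- clinical_table(data.frame(
#'   subject_id = "s1", feature_name = "ALSFRS_Total",
#'   value = c("40", "31"), delta_days = c(92L, 365L)))
#' alsfrs_slope(tab, "s1", "ALSFRS_Total")  # -1.0027 points/month
#' @export
alsfrs_slope <- function(table, subject, frs_feature,
                         window = outcome_window()) {
  rec <- window_records(table, window, subject, frs_feature)
  if (nrow(rec) < 2L) return(NA_real_)
  vals <- numeric_values(rec$value, frs_feature)
  days <- unique(rec$delta_days)
  if (length(days) < 2L) {
    if (length(unique(vals)) > 1L)
      stop("degenerate input: subject ", shQuote(subject),
           " has conflicting ", frs_feature,
           " values on a single in-window day")
    return(NA_real_)
  }
  t1 <- min(days); t2 <- max(days)
  v1 <- mean(vals[rec$delta_days == t1])
  v2 <- mean(vals[rec$delta_days == t2])
  (v2 - v1) / (days_to_months(t2) - days_to_months(t1))
}

#' @rdname alsfrs_slope
#' @param t_days time in days.
#' @export
days_to_months <- function(t_days) t_days / 365 * 12

#' @rdname alsfrs_slope
#' @description `slope_outcomes()` computes the slope for every subject in
#'   the table, dropping subjects for which it is undefined.
#' @export
slope_outcomes <- function(table, frs_feature, window = outcome_window()) {
  subjects <- sort(unique(table$subject_id))
  slopes <- vapply(subjects, function(s)
    alsfrs_slope(table, s, frs_feature, window), numeric(1))
  out <- data.frame(subject_id = subjects, slope = unname(slopes),
                    stringsAsFactors = FALSE)
  out[!is.na(out$slope), , drop = FALSE]
}

#' Censored survival outcome
#'
#' Survival ground truth is the time until death or tracheostomy; subjects
#' without a recorded event are censored at their last clinical visit.
#' The event day is carried by the `delta_days` of the death-feature
#' record.  Subjects whose final record falls on or before day 90 are
#' excluded from the survival analysis (including deaths exactly on day
#' 90, per the quoted rule).
#'
#' @param table a [clinical_table()].
#' @param subject subject identifier.
#' @param death_feature feature name marking death/tracheostomy records.
#' @param exclusion_day final-record cutoff for exclusion (default 90).
#' @return a list with `time_days` and `event` (TRUE = death or
#'   tracheostomy, FALSE = censored), or `NULL` if the subject is excluded.
#' @export
survival_outcome <- function(table, subject, death_feature = "Death",
                             exclusion_day = 90L) {
  sel <- table$subject_id == subject
  if (!any(sel)) return(NULL)
  days <- table$delta_days[sel]
  feats <- table$feature_name[sel]
  death_days <- days[feats == death_feature]
  other_days <- days[feats != death_feature]
  last_day <- max(days)
  if (length(death_days)) {
    ev_day <- min(death_days)
    if (length(other_days) && ev_day < min(other_days))
      stop("subject ", shQuote(subject), ": death day ", ev_day,
           " precedes first record day ", min(other_days))
    if (last_day <= exclusion_day) return(NULL)
    return(list(time_days = as.integer(max(ev_day, 1L)), event = TRUE))
  }
  if (last_day <= exclusion_day) return(NULL)
  list(time_days = as.integer(max(last_day, 1L)), event = FALSE)
}

#' @rdname survival_outcome
#' @description `survival_outcomes()` applies the rule to every subject,
#'   dropping excluded subjects.
#' @export
survival_outcomes <- function(table, death_feature = "Death",
                              exclusion_day = 90L) {
  subjects <- sort(unique(table$subject_id))
  rows <- lapply(subjects, function(s) {
    o <- survival_outcome(table, s, death_feature, exclusion_day)
    if (is.null(o)) return(NULL)
    data.frame(subject_id = s, time_days = o$time_days, event = o$event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), time_days = integer(),
                      event = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname survival_outcome
#' @param months survival horizon in months (e.g. 12, 18, 24).
#' @description `months_to_day_cutoff()` converts a month horizon to the
#'   day cutoff used for survival predictions, `round(m/12 * 365)`.
#' @export
months_to_day_cutoff <- function(months) as.integer(round(months / 12 * 365))
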