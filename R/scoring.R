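#' Raw prediction-assessment metrics
#'
#' Progression (slope) predictions are assessed with three metrics against
#' the ground-truth slopes: root mean square deviation (RMSD), Pearson's
#' correlation (PCC) and the concordance index (CI).  Survival predictions
#' are assessed with the concordance index alone, at each of the 12-, 18-
#' and 24-month horizons.  Inputs are named numeric vectors (names are
#' subject ids); both vectors must cover the same subjects.
#'
#' @param pred named numeric vector of predictions.
#' @param truth named numeric vector of ground-truth values.
#' @return a single number.
#' @export
rmsd <- function(pred, truth) {
  a <- align_by_subject(pred, truth)
  sqrt(mean((a$pred - a$truth)^2))
}

#' @rdname rmsd
#' @export
pearson_cc <- function(pred, truth) {
  a <- align_by_subject(pred, truth)
  if (length(a$pred) < 2L)
    stop("Pearson correlation needs at least two subjects")
  if (stats::sd(a$pred) == 0 || stats::sd(a$truth) == 0)
    stop("Pearson correlation undefined for a constant vector")
  stats::cor(a$pred, a$truth)
}

align_by_subject <- function(pred, truth) {
  if (is.null(names(pred)) || is.null(names(truth)))
    return(list(pred = as.numeric(pred), truth = as.numeric(truth)))
  if (!setequal(names(pred), names(truth)))
    stop("prediction and truth cover different subject sets")
  list(pred = as.numeric(pred[names(truth)]), truth = as.numeric(truth))
}

#' Concordance index with censoring-aware comparability
#'
#' For `n` subjects with predictions `p` and actual values `a`, the
#' tie-free uncensored concordance index is
#' \deqn{CI = \frac{2}{n(n-1)} \sum_{i<j} h(i,j)}
#' where `h(i,j)` is 1 when the pair is ordered the same way in `p` and
#' `a` and 0 when it is ordered oppositely.  With censoring (Harrell's
#' convention) a pair is comparable only when the smaller actual time
#' belongs to an observed event; pairs with tied actual times are not
#' comparable; tied predictions on a comparable pair contribute 0.5.  The
#' denominator is the number of comparable pairs, which reduces to
#' `n(n-1)/2` in the tie-free uncensored case.
#'
#' For survival probabilities, a higher predicted probability paired with
#' a longer observed survival counts as concordant.
#'
#' @param pred numeric predictions (any monotone score).
#' @param actual numeric actual values (times for survival).
#' @param events optional logical vector; `TRUE` = event observed,
#'   `FALSE` = censored at `actual`.  `NULL` means no censoring.
#' @return concordance index in \[0, 1\].
#' @examples
#' concordance_index(c(1, 2, 3), c(2, 1, 3))  # 2/3
#' @export
concordance_index <- function(pred, actual, events = NULL) {
  n <- length(pred)
  if (length(actual) != n) stop("pred and actual differ in length")
  if (n < 2L) stop("concordance index needs at least two subjects")
  ut <- upper.tri(matrix(0, n, n))
  A <- matrix(actual, n, n)
  P <- matrix(pred, n, n)
  ai <- A[ut]; aj <- t(A)[ut]
  pi_ <- P[ut]; pj <- t(P)[ut]
  if (is.null(events)) {
    comparable <- ai != aj
  } else {
    if (length(events) != n) stop("events length mismatch")
    E <- matrix(as.logical(events), n, n)
    ei <- E[ut]; ej <- t(E)[ut]
    comparable <- (ai < aj & ei) | (aj < ai & ej)
  }
  if (!any(comparable))
    stop("concordance index undefined: no comparable pairs")
  concordant <- (ai > aj & pi_ > pj) | (ai < aj & pi_ < pj)
  h <- ifelse(pi_ == pj, 0.5, as.numeric(concordant))
  sum(h[comparable]) / sum(comparable)
}

#' Permutation null distribution of a metric
#'
#' The challenge's z-scores are anchored on an empirical null obtained by
#' shuffling the assignment of ground-truth values to subjects (100,000
#' shuffles in the full-scale analysis) and recomputing the metric on each
#' shuffle.  `truth` may be a numeric vector (slopes) or a data frame
#' whose rows are shuffled jointly (e.g. survival `time_days`/`event`).
#'
#' @param metric function `f(pred, truth)` returning a single number.
#' @param pred predictions passed unchanged to `metric`.
#' @param truth ground truth; rows/elements are shuffled.
#' @param n_perm number of shuffles (>= 100).
#' @param seed integer seed for reproducibility.
#' @return list with `mean`, `sd`, `n_perm` and `n_defined` (shuffles on
#'   which the metric was defined).  Errors if the metric is undefined on
#'   more than half the shuffles.
#' @export
permutation_null <- function(metric, pred, truth, n_perm = 100000L,
                             seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  n <- if (is.data.frame(truth)) nrow(truth) else length(truth)
  vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      shuffled <- if (is.data.frame(truth)) truth[idx, , drop = FALSE]
                  else stats::setNames(as.numeric(truth)[idx], names(truth))
      tryCatch(metric(pred, shuffled), error = function(e) NA_real_)
    }, numeric(1))
  })
  if (mean(is.na(vals)) > 0.5)
    stop("metric undefined on more than half of the shuffles")
  list(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
       n_perm = as.integer(n_perm), n_defined = sum(!is.na(vals)))
}

null_z <- function(score, null) {
  if (!is.finite(null$sd) || null$sd == 0)
    stop("null SD is zero; z-score undefined")
  (score - null$mean) / null$sd
}

#' Challenge score reports
#'
#' `score_slope()` scores a progression prediction set: raw RMSD, PCC and
#' CI, their z-scores against the shuffle null (`z = (score - mean)/SD`),
#' and the combined score `z_slope = z_CI + z_PCC - z_RMSD` (RMSD enters
#' negatively because smaller deviation is better).  `score_survival()`
#' scores the three survival-probability horizons with the
#' censoring-aware concordance index and combines them as
#' `z_survival = z12 + z18 + z24`.  All three metrics are evaluated on the
#' same shuffles, so the component nulls share the permutation stream.
#'
#' @param pred for slope: named numeric vector of predicted slopes; for
#'   survival: data frame with columns `subject_id`, `p12`, `p18`, `p24`
#'   (probabilities in \[0,1\]).
#' @param truth for slope: named numeric vector of ground-truth slopes
#'   (or a data frame `subject_id,slope`); for survival: data frame
#'   `subject_id,time_days,event`.
#' @param n_perm number of shuffles for the null (default 100,000 as in
#'   the full-scale analysis; reduce for desk-scale work).
#' @param seed integer seed.
#' @return an object of class `score_report`.
#' @export
score_slope <- function(pred, truth, n_perm = 100000L, seed = NULL) {
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$slope, truth$subject_id)
  if (is.data.frame(pred))
    pred <- stats::setNames(pred$slope, pred$subject_id)
  a <- align_by_subject(pred, truth)
  p <- a$pred; t0 <- a$truth
  obs <- c(rmsd = rmsd(p, t0), pcc = pearson_cc(p, t0),
           ci = concordance_index(p, t0))
  n <- length(t0)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ts <- t0[sample.int(n)]
      c(tryCatch(rmsd(p, ts), error = function(e) NA_real_),
        tryCatch(pearson_cc(p, ts), error = function(e) NA_real_),
        tryCatch(concordance_index(p, ts), error = function(e) NA_real_))
    }, numeric(3))
  })
  nulls <- apply(draws, 1L, function(v) {
    if (mean(is.na(v)) > 0.5)
      stop("metric undefined on more than half of the shuffles")
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  names(nulls) <- names(obs)
  z <- mapply(null_z, obs, nulls)
  report <- list(kind = "slope", metrics = obs, z = z,
                 combined = unname(z["ci"] + z["pcc"] - z["rmsd"]),
                 null_mean = vapply(nulls, `[[`, numeric(1), "mean"),
                 null_sd = vapply(nulls, `[[`, numeric(1), "sd"),
                 n_perm = as.integer(n_perm), n = n)
  class(report) <- "score_report"
  report
}

#' @rdname score_slope
#' @export
score_survival <- function(pred, truth, n_perm = 100000L, seed = NULL) {
  stopifnot(is.data.frame(pred), is.data.frame(truth))
  horizons <- c("p12", "p18", "p24")
  if (!all(c("subject_id", horizons) %in% names(pred)))
    stop("survival predictions need columns subject_id, p12, p18, p24")
  if (!all(c("subject_id", "time_days", "event") %in% names(truth)))
    stop("survival truth needs columns subject_id, time_days, event")
  if (!setequal(pred$subject_id, truth$subject_id))
    stop("prediction and truth cover different subject sets")
  pr <- as.matrix(pred[match(truth$subject_id, pred$subject_id), horizons])
  if (any(pr < 0 | pr > 1)) stop("survival probabilities must be in [0,1]")
  tm <- truth$time_days; ev <- as.logical(truth$event)
  obs <- vapply(1:3, function(h)
    concordance_index(pr[, h], tm, ev), numeric(1))
  names(obs) <- c("ci12", "ci18", "ci24")
  n <- length(tm)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      vapply(1:3, function(h)
        tryCatch(concordance_index(pr[, h], tm[idx], ev[idx]),
                 error = function(e) NA_real_), numeric(1))
    }, numeric(3))
  })
  nulls <- apply(draws, 1L, function(v) {
    if (mean(is.na(v)) > 0.5)
      stop("metric undefined on more than half of the shuffles")
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  names(nulls) <- names(obs)
  z <- mapply(null_z, obs, nulls)
  names(z) <- c("z12", "z18", "z24")
  report <- list(kind = "survival", metrics = obs, z = z,
                 combined = unname(sum(z)),
                 null_mean = vapply(nulls, `[[`, numeric(1), "mean"),
                 null_sd = vapply(nulls, `[[`, numeric(1), "sd"),
                 n_perm = as.integer(n_perm), n = n)
  class(report) <- "score_report"
  report
}

#' @export
print.score_report <- function(x, ...) {
  cat("Challenge score report (", x$kind, "), n = ", x$n,
      ", n_perm = ", x$n_perm, "\n", sep = "")
  m <- rbind(score = x$metrics, null_mean = x$null_mean,
             null_sd = x$null_sd, z = x$z)
  print(round(m, 4))
  cat("combined z:", format(x$combined, digits = 5), "\n")
  invisible(x)
}

#' Bootstrap head-to-head comparison of two prediction sets
#'
#' The BT score is the percentage of bootstrap resamples (subjects drawn
#' with replacement) in which prediction set A achieves a strictly higher
#' combined z-score than prediction set B.  The null mean and SD for the
#' z-scores are computed once on the full subject set and held fixed
#' across bootstrap samples.
#'
#' @param predA,predB two prediction sets in the format of [score_slope()]
#'   or [score_survival()] according to `kind`.
#' @param truth the shared ground truth.
#' @param kind `"slope"` or `"survival"`.
#' @param n_boot number of bootstrap resamples.
#' @param n_perm shuffles for the fixed null.
#' @param seed integer seed.
#' @return BT percentage in \[0, 100\], with attribute `n_valid` giving
#'   the number of resamples on which both combined scores were defined.
#' @export
bootstrap_compare <- function(predA, predB, truth,
                              kind = c("slope", "survival"),
                              n_boot = 1000L, n_perm = 2000L, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "slope") {
    if (is.data.frame(truth))
      truth <- stats::setNames(truth$slope, truth$subject_id)
    if (is.data.frame(predA))
      predA <- stats::setNames(predA$slope, predA$subject_id)
    if (is.data.frame(predB))
      predB <- stats::setNames(predB$slope, predB$subject_id)
    subjects <- names(truth) %||% as.character(seq_along(truth))
    names(truth) <- subjects
    repA <- score_slope(predA, truth, n_perm, child_seed(seed, 1L))
    repB <- score_slope(predB, truth, n_perm, child_seed(seed, 2L))
    pA <- as.numeric(predA[subjects]); pB <- as.numeric(predB[subjects])
    t0 <- as.numeric(truth)
    combo <- function(p, t, null_mean, null_sd) {
      m <- c(rmsd(p, t), pearson_cc(p, t), concordance_index(p, t))
      z <- (m - null_mean) / null_sd
      z[3] + z[2] - z[1]
    }
    zfunA <- function(i) combo(pA[i], t0[i], repA$null_mean, repA$null_sd)
    zfunB <- function(i) combo(pB[i], t0[i], repB$null_mean, repB$null_sd)
    n <- length(t0)
  } else {
    horizons <- c("p12", "p18", "p24")
    repA <- score_survival(predA, truth, n_perm, child_seed(seed, 1L))
    repB <- score_survival(predB, truth, n_perm, child_seed(seed, 2L))
    ord <- truth$subject_id
    prA <- as.matrix(predA[match(ord, predA$subject_id), horizons])
    prB <- as.matrix(predB[match(ord, predB$subject_id), horizons])
    tm <- truth$time_days; ev <- as.logical(truth$event)
    combo <- function(pr, i, null_mean, null_sd) {
      m <- vapply(1:3, function(h)
        concordance_index(pr[i, h], tm[i], ev[i]), numeric(1))
      sum((m - null_mean) / null_sd)
    }
    zfunA <- function(i) combo(prA, i, repA$null_mean, repA$null_sd)
    zfunB <- function(i) combo(prB, i, repB$null_mean, repB$null_sd)
    n <- length(tm)
  }
  wins <- with_seed(child_seed(seed, 3L), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      zA <- tryCatch(zfunA(i), error = function(e) NA_real_)
      zB <- tryCatch(zfunB(i), error = function(e) NA_real_)
      if (is.na(zA) || is.na(zB)) NA_real_ else as.numeric(zA > zB)
    }, numeric(1))
  })
  valid <- !is.na(wins)
  if (!any(valid)) stop("combined z undefined on every bootstrap sample")
  structure(100 * mean(wins[valid]), n_valid = sum(valid))
}
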