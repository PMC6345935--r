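# Independent brute-force oracles and small fixture builders.

# O(n^2) pair-enumeration concordance index straight from the printed
# h(i,j) definition plus Harrell comparability for censoring.
ci_oracle <- function(pred, actual, events = NULL) {
  n <- length(pred)
  num <- 0; den <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- if (is.null(events)) actual[i] != actual[j] else
      (actual[i] < actual[j] && events[i]) ||
      (actual[j] < actual[i] && events[j])
    if (!comp) next
    den <- den + 1L
    if (pred[i] == pred[j]) num <- num + 0.5
    else if ((actual[i] > actual[j]) == (pred[i] > pred[j])) num <- num + 1
  }
  if (den == 0L) return(NA_real_)
  num / den
}

# Triple-loop co-clustering oracle evaluating m_ij = sum_s log(p / c_s).
m_oracle <- function(submissions, subjects) {
  p <- length(subjects)
  M <- matrix(0, p, p, dimnames = list(subjects, subjects))
  for (s in submissions) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      si <- subjects[i]; sj <- subjects[j]
      if (si %in% names(s) && sj %in% names(s) && s[[si]] == s[[sj]]) {
        cs <- sum(s == s[[si]])
        M[i, j] <- M[i, j] + log(p / cs)
        M[j, i] <- M[i, j]
      }
    }
  }
  M
}

# Random cluster-set submissions over a fixed subject universe.
random_submissions <- function(n_subs, subjects, k = 4L) {
  lapply(seq_len(n_subs), function(s)
    stats::setNames(paste0("c", sample.int(k, length(subjects),
                                           replace = TRUE)), subjects))
}

# Tiny long-format table builder.
make_table <- function(subject, feature, value, day) {
  clinical_table(data.frame(subject_id = subject, feature_name = feature,
                            value = as.character(value),
                            delta_days = as.integer(day)))
}

# Feature matrix with planted cluster structure (unit noise SD).
#   pattern "single": feature j shifts cluster ((j-1) %% k) + 1 by
#     `effect` SD (the planted-effect definition for the FDR screens).
#   pattern "split":  feature j separates two halves of the clusters by
#     `effect` SD (means +/- effect/2 along cycling bipartitions), so
#     every cluster pair is separated by `effect` SD in most features —
#     the separation regime used for the assignment benchmarks.
planted_C <- function(n, k, n_diff, n_null, effect, noise_sd = 1,
                      pattern = c("single", "split")) {
  pattern <- match.arg(pattern)
  g <- rep(seq_len(k), length.out = n)
  subjects <- sprintf("P%04d", seq_len(n))
  rows <- c(sprintf("diff%02d", seq_len(n_diff)),
            sprintf("null%02d", seq_len(n_null)))
  C <- matrix(stats::rnorm(length(rows) * n, 0, noise_sd),
              nrow = length(rows), dimnames = list(rows, subjects))
  for (j in seq_len(n_diff)) {
    if (pattern == "single") {
      target <- ((j - 1L) %% k) + 1L
      C[j, g == target] <- C[j, g == target] + effect
    } else {
      # bipartitions cycle over: low/high half, odd/even, and their xor
      half <- switch((j - 1L) %% 3L + 1L,
                     g <= ceiling(k / 2),
                     g %% 2L == 1L,
                     xor(g <= ceiling(k / 2), g %% 2L == 1L))
      C[j, ] <- C[j, ] + ifelse(half, effect / 2, -effect / 2)
    }
  }
  list(C = C, g = stats::setNames(g, subjects), subjects = subjects,
       diff = rows[seq_len(n_diff)],
       null = if (n_null) rows[n_diff + seq_len(n_null)] else character(0))
}
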