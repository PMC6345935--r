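#' Synthetic cohort specification
#'
#' Defines the study conditions of a synthetic ALS-like cohort with
#' planted patient clusters.  The defaults emulate the four phenotypes
#' reported for the large clinical-trials cohort: a slow-progressing
#' cluster (high baseline function, slope -0.48 points/month, long
#' survival, almost no bulbar onset), an early-stage cluster (high
#' baseline, fast decline -0.93), a late-stage cluster (low baseline
#' ALSFRS-R around 29, short survival) and a fast-progressing cluster
#' (slope -1.05, half bulbar onset).  Each subject follows a linear
#' ALSFRS-R trajectory (points per month) plus Gaussian visit noise,
#' truncated to the 0-48 scale; survival times are exponential with a
#' cluster-specific hazard (events/day) and administratively censored;
#' static continuous features carry per-cluster mean shifts in SD units;
#' discrete features follow per-cluster category probabilities; records
#' are masked at the missingness rate.
#'
#' @param n_subjects cohort size.
#' @param k_true number of planted clusters.
#' @param cluster_weights mixing weights (sum to 1).
#' @param baseline per-cluster ALSFRS-R intercept at day 0 (points).
#' @param slope per-cluster progression slope (points/month, negative).
#' @param residual_sd visit-level Gaussian noise SD (points).
#' @param hazard per-cluster death/tracheostomy hazard (events/day).
#' @param censor_day administrative censoring day.
#' @param n_diff_features number of planted differential continuous
#'   features.
#' @param effect_size planted mean shift in SD units.
#' @param n_null_features number of null continuous features.
#' @param discrete_probs named list of per-cluster category probability
#'   matrices (categories x clusters); the default plants a bulbar/limb
#'   site-of-onset feature (bulbar fractions 0.03/0.20/0.20/0.50 across
#'   the four clusters), one more differential discrete feature, and
#'   three null discrete features.
#' @param visit_interval_days mean spacing between clinic visits.
#' @param visit_jitter_sd SD of the spacing jitter (days).
#' @param missingness probability that any single feature record is
#'   dropped.
#' @param seed integer seed stored in the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 400L, k_true = 4L,
                        cluster_weights = NULL,
                        baseline = c(40.25, 41, 29, 35.75),
                        slope = c(-0.48, -0.93, -0.70, -1.05),
                        residual_sd = 1.5,
                        hazard = c(0.00047, 0.00063, 0.00127, 0.00127),
                        censor_day = 730L,
                        n_diff_features = 5L, effect_size = 1,
                        n_null_features = 50L,
                        discrete_probs = NULL,
                        visit_interval_days = 30, visit_jitter_sd = 5,
                        missingness = 0.1, seed = NULL) {
  k <- as.integer(k_true)
  cluster_weights <- cluster_weights %||% rep(1 / k, k)
  if (length(cluster_weights) != k || abs(sum(cluster_weights) - 1) > 1e-8)
    stop("cluster_weights must have length k_true and sum to 1")
  baseline <- rep_len(baseline, k); slope <- rep_len(slope, k)
  hazard <- rep_len(hazard, k)
  if (any(hazard < 0) || residual_sd < 0)
    stop("rates and SDs must be non-negative")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must be in [0, 1)")
  if (is.null(discrete_probs)) {
    bulbar <- rep_len(c(0.03, 0.20, 0.20, 0.50), k)
    cat3 <- function(p1) rbind(p1, (1 - p1) * 0.6, (1 - p1) * 0.4)
    discrete_probs <- list(
      site_of_onset = rbind(bulbar = bulbar, limb = 1 - bulbar),
      stage_group = cat3(rep_len(c(0.6, 0.3, 0.2, 0.4), k)),
      sex = rbind(F = rep(0.4, k), M = rep(0.6, k)),
      cohort_site = matrix(1 / 3, 3, k,
                           dimnames = list(c("a", "b", "c"), NULL)),
      riluzole = rbind(no = rep(0.3, k), yes = rep(0.7, k)))
  }
  for (nm in names(discrete_probs)) {
    pm <- discrete_probs[[nm]]
    if (ncol(pm) != k || any(abs(colSums(pm) - 1) > 1e-8))
      stop("discrete_probs[[", nm, "]] must be categories x k with ",
           "columns summing to 1")
  }
  structure(list(n_subjects = as.integer(n_subjects), k_true = k,
                 cluster_weights = cluster_weights, baseline = baseline,
                 slope = slope, residual_sd = residual_sd,
                 hazard = hazard, censor_day = as.integer(censor_day),
                 n_diff_features = as.integer(n_diff_features),
                 effect_size = effect_size,
                 n_null_features = as.integer(n_null_features),
                 discrete_probs = discrete_probs,
                 visit_interval_days = visit_interval_days,
                 visit_jitter_sd = visit_jitter_sd,
                 missingness = missingness, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' Draws a long-format clinical table plus the planted ground truth: the
#' true cluster labels, the true progression slopes (points/month) and
#' the true censored survival outcomes.  ALSFRS-R visits follow a
#' jittered schedule over days 0-365, truncated at death; the death
#' record (feature `"Death"`) is carried at its `delta_days`.  Planted
#' continuous feature `j` shifts its mean by `effect_size` SD units in
#' cluster `((j-1) mod k) + 1`; null features are standard normal in all
#' clusters.  Fully reproducible under the spec's (or the argument's)
#' seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a list with `table` (a [clinical_table()]), `dictionary`,
#'   `labels` (named integer), `slope_true` (named numeric),
#'   `survival_true` (data frame `subject_id,time_days,event`).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    n <- spec$n_subjects; k <- spec$k_true
    subjects <- sprintf("S%04d", seq_len(n))
    labels <- sample.int(k, n, replace = TRUE, prob = spec$cluster_weights)
    names(labels) <- subjects
    # survival: exponential with cluster hazard, administrative censoring
    haz <- spec$hazard[labels]
    latent <- ifelse(haz > 0, stats::rexp(n, rate = pmax(haz, 1e-300)), Inf)
    event <- haz > 0 & latent <= spec$censor_day
    time_days <- pmax(1L, as.integer(round(pmin(latent, spec$censor_day))))
    rec <- list()
    add <- function(subject, feature, value, day)
      rec[[length(rec) + 1L]] <<- data.frame(
        subject_id = subject, feature_name = feature,
        value = as.character(value), delta_days = as.integer(day),
        stringsAsFactors = FALSE)
    slope_true <- stats::setNames(spec$slope[labels], subjects)
    for (i in seq_len(n)) {
      s <- subjects[i]; c_id <- labels[i]
      horizon <- min(365L, time_days[i])
      day <- 0L; days <- integer(0)
      while (day <= horizon) {
        days <- c(days, day)
        step <- max(1, round(stats::rnorm(1, spec$visit_interval_days,
                                          spec$visit_jitter_sd)))
        day <- day + as.integer(step)
      }
      vals <- spec$baseline[c_id] +
        spec$slope[c_id] * days_to_months(days) +
        stats::rnorm(length(days), 0, spec$residual_sd)
      vals <- pmin(pmax(vals, 0), 48)
      add(rep(s, length(days)), "ALSFRS_R_Total", vals, days)
      if (event[i]) add(s, "Death", "death", time_days[i])
    }
    # static continuous features, recorded once at day 0
    n_diff <- spec$n_diff_features; n_null <- spec$n_null_features
    cont_names <- c(sprintf("diff_feat_%02d", seq_len(n_diff)),
                    sprintf("null_feat_%02d", seq_len(n_null)))
    for (j in seq_len(n_diff)) {
      shift_cluster <- ((j - 1L) %% k) + 1L
      mu <- ifelse(labels == shift_cluster, spec$effect_size, 0)
      add(subjects, cont_names[j], round(stats::rnorm(n, mu, 1), 5),
          rep(0L, n))
    }
    for (j in seq_len(n_null))
      add(subjects, cont_names[n_diff + j],
          round(stats::rnorm(n, 0, 1), 5), rep(0L, n))
    for (nm in names(spec$discrete_probs)) {
      pm <- spec$discrete_probs[[nm]]
      cats <- rownames(pm) %||% paste0("c", seq_len(nrow(pm)))
      v <- vapply(labels, function(c_id)
        sample(cats, 1L, prob = pm[, c_id]), character(1))
      add(subjects, nm, v, rep(0L, n))
    }
    tab <- do.call(rbind, rec)
    # missingness: drop feature records at random (never death records)
    if (spec$missingness > 0) {
      droppable <- tab$feature_name != "Death"
      drop <- droppable & stats::runif(nrow(tab)) < spec$missingness
      tab <- tab[!drop, , drop = FALSE]
    }
    dict <- feature_dictionary(
      c("ALSFRS_R_Total", cont_names, names(spec$discrete_probs), "Death"),
      c("continuous", rep("continuous", length(cont_names)),
        rep("discrete", length(spec$discrete_probs)), "discrete"),
      c("points", rep("sd units", length(cont_names)),
        rep("", length(spec$discrete_probs)), ""))
    list(table = clinical_table(tab), dictionary = dict, labels = labels,
         slope_true = slope_true,
         survival_true = data.frame(subject_id = subjects,
                                    time_days = time_days, event = event,
                                    stringsAsFactors = FALSE),
         diff_features = cont_names[seq_len(n_diff)],
         null_features = cont_names[n_diff + seq_len(n_null)])
  })
}

#' Synthetic solver-submission specification
#'
#' Emulates the cluster-set submissions of independent solvers: each
#' structured solver reports the planted labels with a fraction
#' `label_noise` of subjects relabeled uniformly at random, optionally
#' splitting or merging one planted cluster; `n_random_solvers`
#' additional solvers assign subjects uniformly at random.
#'
#' @param n_solvers number of structured solvers.
#' @param label_noise fraction of subjects relabeled per solver, in
#'   \[0, 1\].
#' @param split_merge_prob probability that a solver splits or merges one
#'   cluster.
#' @param n_random_solvers number of purely random solvers.
#' @param seed integer seed stored in the spec.
#' @return an object of class `solver_spec`.
#' @export
solver_spec <- function(n_solvers = 30L, label_noise = 0.2,
                        split_merge_prob = 0, n_random_solvers = 3L,
                        seed = NULL) {
  for (p in c(label_noise, split_merge_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  structure(list(n_solvers = as.integer(n_solvers),
                 label_noise = label_noise,
                 split_merge_prob = split_merge_prob,
                 n_random_solvers = as.integer(n_random_solvers),
                 seed = seed),
            class = "solver_spec")
}

#' @rdname solver_spec
#' @param true_labels named integer vector of planted cluster labels.
#' @param spec a `solver_spec`.
#' @return `generate_solver_submissions()` returns a named list of
#'   cluster sets (see [read_submissions()]).
#' @export
generate_solver_submissions <- function(true_labels, spec, seed = NULL) {
  stopifnot(inherits(spec, "solver_spec"))
  seed <- seed %||% spec$seed
  subjects <- names(true_labels)
  n <- length(true_labels)
  k <- max(as.integer(true_labels))
  with_seed(seed, {
    subs <- list()
    for (s in seq_len(spec$n_solvers)) {
      lab <- as.integer(true_labels)
      if (spec$label_noise > 0) {
        flip <- stats::runif(n) < spec$label_noise
        lab[flip] <- sample.int(k, sum(flip), replace = TRUE)
      }
      if (spec$split_merge_prob > 0 &&
          stats::runif(1) < spec$split_merge_prob) {
        if (stats::runif(1) < 0.5 && k >= 2L) {  # merge two clusters
          pair <- sample.int(k, 2L)
          lab[lab == pair[2L]] <- pair[1L]
        } else {  # split one cluster in two
          c_id <- sample.int(k, 1L)
          members <- which(lab == c_id)
          if (length(members) >= 2L) {
            half <- sample(members, floor(length(members) / 2))
            lab[half] <- k + 1L
          }
        }
      }
      subs[[sprintf("solver%03d", s)]] <-
        stats::setNames(paste0("cl", lab), subjects)
    }
    for (r in seq_len(spec$n_random_solvers)) {
      lab <- sample.int(k, n, replace = TRUE)
      subs[[sprintf("random%03d", r)]] <-
        stats::setNames(paste0("cl", lab), subjects)
    }
    subs
  })
}
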