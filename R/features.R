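#' Summarize longitudinal features into per-patient values
#'
#' Longitudinal clinical variables are collapsed into one value per
#' patient per time window: continuous features yield one row per
#' summary statistic (mean, min, max of the in-window values by
#' default), discrete features yield their modal in-window category
#' (ties broken by sorted category order).  Patients with no in-window
#' record are missing (`NA`).  The two windows of the challenge design
#' are the observation period (days 0-91) and the outcome period (days
#' 92-365).
#'
#' @param table a [clinical_table()].
#' @param dictionary a [feature_dictionary()] classifying each feature.
#' @param window a [time_window()].
#' @param stats summary statistics for continuous features.
#' @return an object of class `feature_summary`: list with `C` (numeric
#'   matrix, rows = `feature.stat`, columns = subjects), `D` (character
#'   matrix, rows = discrete features) and `window`.
#' @export
summarize_features <- function(table, dictionary,
                               window = observation_window(),
                               stats = c("mean", "min", "max")) {
  stopifnot(inherits(dictionary, "feature_dictionary"))
  stats <- match.arg(stats, c("mean", "min", "max"), several.ok = TRUE)
  subjects <- sort(unique(table$subject_id))
  in_win <- table$delta_days >= window$start_day &
    table$delta_days <= window$end_day
  tw <- table[in_win, , drop = FALSE]
  kind <- stats::setNames(dictionary$kind, dictionary$feature_name)
  feats <- intersect(dictionary$feature_name, unique(tw$feature_name))
  cont <- feats[kind[feats] == "continuous"]
  disc <- feats[kind[feats] == "discrete"]
  stat_fun <- list(mean = mean, min = min, max = max)
  C <- matrix(NA_real_, nrow = length(cont) * length(stats),
              ncol = length(subjects),
              dimnames = list(as.vector(t(outer(cont, stats, paste, sep = "."))),
                              subjects))
  for (f in cont) {
    sel <- tw$feature_name == f
    vals <- split(numeric_values(tw$value[sel], f), tw$subject_id[sel])
    for (st in stats) {
      row <- paste(f, st, sep = ".")
      C[row, names(vals)] <- vapply(vals, stat_fun[[st]], numeric(1))
    }
  }
  D <- matrix(NA_character_, nrow = length(disc), ncol = length(subjects),
              dimnames = list(disc, subjects))
  for (f in disc) {
    sel <- tw$feature_name == f
    vals <- split(tw$value[sel], tw$subject_id[sel])
    D[f, names(vals)] <- vapply(vals, function(v) {
      tab <- sort(table(v), decreasing = TRUE)
      names(tab)[which(tab == max(tab))[1L]]  # modal, ties by sorted order
    }, character(1))
  }
  structure(list(C = C, D = D, window = window, subjects = subjects),
            class = "feature_summary")
}

#' Per-feature test statistics across consensus clusters
#'
#' `anova_statistic()` is the classical one-way ANOVA F for a continuous
#' feature across clusters; `fisher_statistic()` is the Fisher exact test
#' p-value on the category-by-cluster contingency table of a discrete
#' feature (Freeman-Halton style via the hybrid algorithm for tables
#' larger than 2x2).  Both use pairwise-complete (non-missing) entries
#' and return `NA` when the statistic is undefined (all values in one
#' cluster, fewer than 2 categories, ...).
#'
#' @param values numeric (ANOVA) or character (Fisher) feature values,
#'   one per subject; `NA` allowed.
#' @param g cluster design: vector of cluster ids aligned with `values`.
#' @return F statistic, or exact-test p-value, or `NA`.
#' @export
anova_statistic <- function(values, g) {
  ok <- !is.na(values) & !is.na(g)
  v <- as.numeric(values[ok])
  gg <- droplevels(factor(g[ok]))
  n <- length(v); k <- nlevels(gg)
  if (n < 3L || k < 2L || n - k < 1L) return(NA_real_)
  gm <- mean(v)
  means <- vapply(split(v, gg), mean, numeric(1))
  sizes <- tabulate(gg)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((v - means[as.integer(gg)])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @rdname anova_statistic
#' @export
fisher_statistic <- function(values, g) {
  ok <- !is.na(values) & !is.na(g)
  tab <- table(factor(values[ok]), factor(g[ok]))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  res <- tryCatch(
    stats::fisher.test(tab, hybrid = nrow(tab) > 2L || ncol(tab) > 2L),
    error = function(e)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 2000L))
  res$p.value
}

welch_t <- function(v, in_a, in_b) {
  va <- v[in_a & !is.na(v)]; vb <- v[in_b & !is.na(v)]
  if (length(va) < 2L || length(vb) < 2L) return(NA_real_)
  se2 <- stats::var(va) / length(va) + stats::var(vb) / length(vb)
  if (se2 == 0) return(if (mean(va) == mean(vb)) 0 else Inf * sign(mean(va) - mean(vb)))
  (mean(va) - mean(vb)) / sqrt(se2)
}

# Relative rank of x within a pooled reference distribution:
# fraction of reference values <= x (higher = more extreme).
relative_rank <- function(x, ref_sorted) {
  findInterval(x, ref_sorted) / length(ref_sorted)
}

sam_fdr <- function(obs, perm_matrix, n_perm) {
  # obs: vector of observed values (higher = more extreme);
  # perm_matrix: same units x n_perm of permuted values (NA allowed).
  perm_sorted <- sort(perm_matrix[!is.na(perm_matrix)])
  obs_sorted <- sort(obs)
  count_ge <- function(x, sorted_vals)
    length(sorted_vals) - findInterval(x, sorted_vals, left.open = TRUE)
  n_false <- count_ge(obs, perm_sorted) / n_perm
  n_true <- count_ge(obs, obs_sorted)
  raw <- pmin(pmax(n_false / n_true, 0), 1)
  # q-value convention: FDR at score s is the minimum raw FDR over all
  # call thresholds <= s, which makes it monotone non-increasing in s
  ord <- order(obs)
  fdr <- numeric(length(obs))
  fdr[ord] <- cummin(raw[ord])
  fdr
}

#' Integrated permutation-rank FDR across continuous and discrete features
#'
#' Screens features that are differentially distributed across consensus
#' clusters.  Each feature row is shuffled against the fixed design `g`
#' `n_perm` times; ANOVA F (continuous rows of `C`) and Fisher exact
#' p-values mapped to `-log(p)` (discrete rows of `D`) are computed for
#' the observed and every permuted row.  Observed and permuted statistics
#' are converted to relative ranks within their own family's pooled
#' permutation distribution, the ranks of both families are pooled, and a
#' SAM-style FDR is attached to every feature:
#' `FDR(r) = (mean permuted count >= r) / (observed count >= r)`,
#' clipped to \[0, 1\] and monotonized.  Features whose observed
#' statistic is undefined are excluded and reported.
#'
#' @param C numeric matrix, continuous features x subjects (or a
#'   `feature_summary`, in which case `D` is taken from it too).
#' @param D optional character matrix of discrete features x subjects.
#' @param g named cluster design covering the columns of `C`/`D`.
#' @param n_perm number of row permutations (>= 10; 100 in the original
#'   analysis).
#' @param seed integer seed (fixed seed gives bit-identical FDR tables).
#' @return an object of class `feature_fdr`: list with `table` (feature,
#'   family, statistic, rank, fdr), `excluded`, and the permutation
#'   bookkeeping reused by [pairwise_ttest_fdr()].
#' @export
integrated_rank_fdr <- function(C, D = NULL, g, n_perm = 100L, seed = NULL) {
  if (inherits(C, "feature_summary")) {
    if (is.null(D)) D <- C$D
    C <- C$C
  }
  if (n_perm < 10L) stop("n_perm must be at least 10")
  subjects <- colnames(C) %||% names(g)
  if (is.null(names(g))) names(g) <- subjects
  miss <- setdiff(subjects, names(g))
  if (length(miss)) stop("design g misses subject(s): ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  g <- g[subjects]
  n <- length(subjects)
  if (!is.null(D) && nrow(D) == 0L) D <- NULL
  families <- list()
  perm_idx <- list()
  with_seed(seed, {
    run_family <- function(X, stat_fun) {
      if (is.null(X)) return(NULL)
      obs <- apply(X, 1L, stat_fun, g = g)
      idx <- lapply(seq_len(nrow(X)), function(i)
        vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
      perm <- t(vapply(seq_len(nrow(X)), function(i) {
        v <- X[i, ]
        vapply(seq_len(n_perm), function(b)
          stat_fun(v[idx[[i]][, b]], g = g), numeric(1))
      }, numeric(n_perm)))
      list(obs = obs, perm = perm, idx = stats::setNames(idx, rownames(X)))
    }
    families$continuous <- run_family(C, anova_statistic)
    families$discrete <- run_family(
      D, function(values, g) {
        p <- fisher_statistic(values, g)
        if (is.na(p)) NA_real_ else -log(pmax(p, .Machine$double.xmin))
      })
  })
  rank_family <- function(fam) {
    if (is.null(fam)) return(NULL)
    keep <- !is.na(fam$obs)
    ref <- sort(fam$perm[keep, , drop = FALSE][!is.na(fam$perm[keep, ])])
    r_obs <- relative_rank(fam$obs[keep], ref)
    r_perm <- matrix(relative_rank(fam$perm[keep, , drop = FALSE], ref),
                     nrow = sum(keep))
    r_perm[is.na(r_perm)] <- 0
    list(features = names(fam$obs)[keep], excluded = names(fam$obs)[!keep],
         obs = fam$obs[keep], r_obs = r_obs, r_perm = r_perm)
  }
  rc <- rank_family(families$continuous)
  rd <- rank_family(families$discrete)
  feature <- c(rc$features, rd$features)
  family <- c(rep("continuous", length(rc$features)),
              rep("discrete", length(rd$features)))
  statistic <- c(rc$obs, rd$obs)
  r_obs <- c(rc$r_obs, rd$r_obs)
  r_perm <- rbind(rc$r_perm, rd$r_perm)
  if (!length(feature)) stop("no feature with a defined statistic")
  fdr <- sam_fdr(r_obs, r_perm, n_perm)
  tab <- data.frame(feature = feature, family = family,
                    statistic = unname(statistic), rank = unname(r_obs),
                    fdr = unname(fdr), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 excluded = c(rc$excluded, rd$excluded),
                 g = g, n_perm = as.integer(n_perm),
                 c_perm_idx = families$continuous$idx),
            class = "feature_fdr")
}

#' @export
print.feature_fdr <- function(x, ...) {
  cat("Integrated permutation-rank FDR over", nrow(x$table), "features (",
      x$n_perm, "permutations )\n")
  cat("significant at FDR < 5%:", sum(x$table$fdr < 0.05), "\n")
  if (length(x$excluded))
    cat("excluded (undefined statistic):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise cluster comparisons for globally significant features
#'
#' Applies the "ANOVA trick": Welch t-tests between every pair of
#' clusters are run only for continuous features that reached global
#' FDR < `alpha` in [integrated_rank_fdr()], keeping the implicit
#' multiple-testing burden small.  The same row permutations as in the
#' global screen are reused to convert `|t|` statistics into SAM-style
#' FDRs, restricted to the gated features.  The direction records which
#' cluster has the higher mean.
#'
#' @param C numeric matrix of continuous features x subjects (or a
#'   `feature_summary`).
#' @param g named cluster design.
#' @param global_result result of [integrated_rank_fdr()].
#' @param alpha gating and significance threshold (default 0.05).
#' @return an object of class `pairwise_fdr`: data frame with columns
#'   `feature`, `cluster_a`, `cluster_b`, `t`, `fdr`, `direction`,
#'   `significant`, plus a `skipped` attribute listing pairs with too few
#'   observations.
#' @export
pairwise_ttest_fdr <- function(C, g, global_result, alpha = 0.05) {
  if (inherits(C, "feature_summary")) C <- C$C
  stopifnot(inherits(global_result, "feature_fdr"))
  g <- global_result$g
  tab <- global_result$table
  gated <- tab$feature[tab$family == "continuous" & tab$fdr < alpha]
  clusters <- sort(unique(as.integer(g)))
  pairs <- utils::combn(clusters, 2L)
  rows <- list(); skipped <- list()
  obs_t <- c(); perm_t <- NULL
  n_perm <- global_result$n_perm
  for (f in gated) {
    v <- C[f, ]
    idx <- global_result$c_perm_idx[[f]]
    for (pcol in seq_len(ncol(pairs))) {
      a <- pairs[1L, pcol]; b <- pairs[2L, pcol]
      in_a <- as.integer(g) == a; in_b <- as.integer(g) == b
      t_obs <- welch_t(v, in_a, in_b)
      if (is.na(t_obs)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(feature = f, cluster_a = a, cluster_b = b)
        next
      }
      t_perm <- vapply(seq_len(n_perm), function(bb)
        abs(welch_t(v[idx[, bb]], in_a, in_b)), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, cluster_a = a, cluster_b = b, t = t_obs,
        direction = if (t_obs >= 0) a else b, stringsAsFactors = FALSE)
      obs_t <- c(obs_t, abs(t_obs))
      perm_t <- rbind(perm_t, t_perm)
    }
  }
  if (!length(rows)) {
    out <- data.frame(feature = character(), cluster_a = integer(),
                      cluster_b = integer(), t = numeric(),
                      fdr = numeric(), direction = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    perm_t[is.na(perm_t)] <- 0
    out$fdr <- sam_fdr(obs_t, perm_t, n_perm)
    out$significant <- out$fdr < alpha
    out <- out[, c("feature", "cluster_a", "cluster_b", "t", "fdr",
                   "direction", "significant")]
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_fdr", "data.frame")
  out
}

#' Rank-order heatmap matrix from pairwise comparisons
#'
#' Collapses pairwise comparisons into a per-cluster rank: for every
#' significant pair `(a, b)` where the feature is higher in `a`, the rank
#' of `a` increases by 1 and the rank of `b` decreases by 1.  Each
#' feature row is then linearly rescaled to \[-1, +1\]; rows with no
#' significant comparison stay all-zero.
#'
#' @param pairwise a `pairwise_fdr` object.
#' @param clusters optional integer vector of cluster ids (defaults to
#'   those appearing in `pairwise`).
#' @return numeric matrix, features x clusters, entries in \[-1, 1\].
#' @export
heatmap_matrix <- function(pairwise, clusters = NULL) {
  stopifnot(inherits(pairwise, "pairwise_fdr"))
  if (is.null(clusters))
    clusters <- sort(unique(c(pairwise$cluster_a, pairwise$cluster_b)))
  feats <- unique(pairwise$feature)
  H <- matrix(0, length(feats), length(clusters),
              dimnames = list(feats, as.character(clusters)))
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$cluster_a[i]; b <- sig$cluster_b[i]
    winner <- sig$direction[i]
    loser <- if (winner == a) b else a
    H[sig$feature[i], as.character(winner)] <-
      H[sig$feature[i], as.character(winner)] + 1
    H[sig$feature[i], as.character(loser)] <-
      H[sig$feature[i], as.character(loser)] - 1
  }
  t(apply(H, 1L, function(r) {
    if (all(r == 0)) return(r)
    -1 + 2 * (r - min(r)) / (max(r) - min(r))
  }))
}

#' Feature-usage tally across submitted algorithms
#'
#' Challenge submissions were restricted to a small number of predictive
#' features (at most 6); this tallies, for each feature, the fraction of
#' submissions that selected it, per sub-challenge and averaged across
#' sub-challenges.
#'
#' @param selections list of character vectors, one per submission.
#' @param subchallenge optional vector assigning each submission to a
#'   sub-challenge.
#' @param max_features validation cap on list length (default 6).
#' @return data frame with a `probability` column (and per-sub-challenge
#'   columns plus their `average` when `subchallenge` is given), sorted
#'   by decreasing probability.
#' @export
feature_usage_tally <- function(selections, subchallenge = NULL,
                                max_features = 6L) {
  lens <- lengths(selections)
  if (any(lens > max_features))
    stop("submission selects more than ", max_features, " features")
  feats <- sort(unique(unlist(selections)))
  prob_in <- function(lists) vapply(feats, function(f)
    mean(vapply(lists, function(l) f %in% l, logical(1))), numeric(1))
  if (is.null(subchallenge)) {
    out <- data.frame(feature = feats, probability = prob_in(selections),
                      stringsAsFactors = FALSE)
    return(out[order(-out$probability, out$feature), ])
  }
  groups <- split(selections, subchallenge)
  per_group <- vapply(groups, prob_in, numeric(length(feats)))
  per_group <- matrix(per_group, nrow = length(feats),
                      dimnames = list(feats, names(groups)))
  out <- data.frame(feature = feats, per_group,
                    average = rowMeans(per_group), stringsAsFactors = FALSE)
  out[order(-out$average, out$feature), ]
}
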