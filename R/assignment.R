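#' Uncentered correlation
#'
#' Cosine-like similarity without mean-centering,
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, computed over the
#' pairwise-complete (both non-missing) components.  Used to match
#' z-normalized patient feature vectors against cluster profiles.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @return similarity in \[-1, 1\].
#' @examples
#' uncentered_correlation(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no overlapping non-missing components")
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("uncentered correlation undefined for a zero-norm vector")
  sum(x * y) / (nx * ny)
}

#' Cluster profiles for assigning new patients
#'
#' Builds the re-clustering model: selects the most discriminating
#' continuous features (up to `max_features` features with FDR at or
#' below `fdr_cap`, the original analysis used the top 20 features at
#' FDR < 0.01%), z-normalizes each by its training-cohort mean and
#' standard deviation, and stores the per-cluster mean z-vector as the
#' cluster centroid.  Zero-variance features are dropped with a warning.
#'
#' @param C numeric matrix of continuous features x subjects (or a
#'   `feature_summary`).
#' @param labels named cluster labels of the training subjects.
#' @param fdr_result a `feature_fdr` covering the rows of `C`.
#' @param max_features maximum number of profile features.
#' @param fdr_cap FDR cutoff for selection (default 1e-4, i.e. 0.01%).
#' @return an object of class `cluster_profiles` with components
#'   `features`, `center`, `scale`, `centroids` (clusters x features).
#' @export
build_profiles <- function(C, labels, fdr_result, max_features = 20L,
                           fdr_cap = 1e-4) {
  if (inherits(C, "feature_summary")) C <- C$C
  stopifnot(inherits(fdr_result, "feature_fdr"))
  tab <- fdr_result$table
  tab <- tab[tab$family == "continuous" & tab$feature %in% rownames(C), ]
  tab <- tab[tab$fdr <= fdr_cap, , drop = FALSE]
  if (!nrow(tab))
    stop("no feature passes fdr_cap = ", fdr_cap,
         "; relax fdr_cap (or lower max_features expectations)")
  tab <- tab[order(tab$fdr, -tab$statistic, tab$feature), , drop = FALSE]
  feats <- utils::head(tab$feature, max_features)
  subjects <- intersect(colnames(C), names(labels))
  Xs <- C[feats, subjects, drop = FALSE]
  ctr <- apply(Xs, 1L, mean, na.rm = TRUE)
  scl <- apply(Xs, 1L, stats::sd, na.rm = TRUE)
  keep <- is.finite(scl) & scl > 0
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(feats[!keep], collapse = ", "))
    feats <- feats[keep]; Xs <- Xs[keep, , drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
    if (!length(feats)) stop("all selected features have zero variance")
  }
  Z <- (Xs - ctr) / scl
  g <- as.integer(labels[subjects])
  clusters <- sort(unique(g))
  centroids <- matrix(NA_real_, length(clusters), length(feats),
                      dimnames = list(as.character(clusters), feats))
  for (i in seq_along(clusters))
    centroids[i, ] <- rowMeans(Z[, g == clusters[i], drop = FALSE],
                               na.rm = TRUE)
  structure(list(features = feats, center = ctr, scale = scl,
                 centroids = centroids, clusters = clusters),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("Cluster profiles:", length(x$features), "features,",
      length(x$clusters), "clusters\n")
  cat("features:", paste(utils::head(x$features, 8L), collapse = ", "),
      if (length(x$features) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Assign patients to consensus clusters
#'
#' New patients are z-normalized with the training normalization and
#' assigned to the cluster whose centroid gives the highest uncentered
#' correlation (ties to the lowest cluster index).  Patients observing
#' fewer than `min_overlap` of the profile features are unassignable
#' (`NA`).
#'
#' @param object a `cluster_profiles` model.
#' @param newdata numeric matrix features x patients (rows matched to the
#'   profile features by name), or a single named vector.
#' @param min_overlap minimum fraction of profile features that must be
#'   observed (default 0.25).
#' @param ... unused.
#' @return a data frame with `subject_id`, `cluster` and one correlation
#'   column per cluster.
#' @export
predict.cluster_profiles <- function(object, newdata, min_overlap = 0.25,
                                     ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "patient"))
  if (inherits(newdata, "feature_summary")) newdata <- newdata$C
  found <- intersect(object$features, rownames(newdata))
  if (!length(found)) stop("newdata contains none of the profile features")
  X <- matrix(NA_real_, length(object$features), ncol(newdata),
              dimnames = list(object$features, colnames(newdata)))
  X[found, ] <- as.matrix(newdata[found, , drop = FALSE])
  Z <- (X - object$center) / object$scale
  k <- length(object$clusters)
  cors <- matrix(NA_real_, ncol(Z), k,
                 dimnames = list(colnames(Z),
                                 paste0("cor", object$clusters)))
  cluster <- rep(NA_integer_, ncol(Z))
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    if (mean(!is.na(z)) < min_overlap) next
    cc <- vapply(seq_len(k), function(c_idx)
      tryCatch(uncentered_correlation(z, object$centroids[c_idx, ]),
               error = function(e) NA_real_), numeric(1))
    cors[j, ] <- cc
    if (all(is.na(cc))) next
    cluster[j] <- object$clusters[which.max(replace(cc, is.na(cc), -Inf))]
  }
  data.frame(subject_id = colnames(Z), cluster = cluster, cors,
             stringsAsFactors = FALSE)
}

#' @rdname predict.cluster_profiles
#' @param profiles a `cluster_profiles` model.
#' @export
assign_clusters <- function(newdata, profiles, min_overlap = 0.25) {
  predict(profiles, newdata, min_overlap = min_overlap)
}

#' Cross-validated assignment accuracy
#'
#' Estimates how reliably patients can be re-associated with their
#' consensus cluster from clinical features alone.  In each of `folds`
#' cross-validation steps, the held-out patients are removed *before*
#' the discriminating features are determined: the permutation-rank FDR
#' screen and the cluster profiles are recomputed on the training
#' portion, the held-out patients are assigned, and accuracy is the
#' pooled fraction of correct assignments among assigned patients
#' (optionally restricted to core patients).  Folds are stratified by
#' consensus cluster; a fold whose training portion misses a cluster is
#' skipped with a warning.
#'
#' @param C numeric matrix of continuous features x subjects (or a
#'   `feature_summary`).
#' @param labels named consensus labels.
#' @param D optional discrete feature matrix entering the global screen.
#' @param folds number of folds (default 10).
#' @param core_mask optional named logical; when given, accuracy counts
#'   only core patients.
#' @param n_perm permutations for the per-fold feature screen.
#' @param fdr_cap,max_features,min_overlap passed to [build_profiles()]
#'   and [predict.cluster_profiles()].
#' @param seed integer seed (fixes the fold split and the screens).
#' @return a list with `accuracy`, `n_correct`, `n_assigned`, `n_held_out`
#'   and the per-fold table.
#' @export
crossval_accuracy <- function(C, labels, D = NULL, folds = 10L,
                              core_mask = NULL, n_perm = 50L,
                              fdr_cap = 1e-4, max_features = 20L,
                              min_overlap = 0.25, seed = NULL) {
  if (inherits(C, "feature_summary")) {
    if (is.null(D)) D <- C$D
    C <- C$C
  }
  if (folds < 2L) stop("folds must be at least 2")
  subjects <- intersect(colnames(C), names(labels))
  g <- as.integer(labels[subjects])
  fold_of <- integer(length(subjects))
  with_seed(child_seed(seed, 1L), {
    for (c_id in unique(g)) {  # stratified by consensus cluster
      members <- which(g == c_id)
      fold_of[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
  })
  per_fold <- list()
  n_correct <- 0L; n_assigned <- 0L; n_held <- 0L
  for (f in seq_len(folds)) {
    test <- subjects[fold_of == f]
    train <- subjects[fold_of != f]
    if (length(unique(g[fold_of != f])) < length(unique(g))) {
      warning("fold ", f, " misses a cluster in training; skipped")
      next
    }
    fdr_f <- tryCatch(
      integrated_rank_fdr(C[, train, drop = FALSE],
                          if (!is.null(D)) D[, train, drop = FALSE],
                          g = labels[train], n_perm = n_perm,
                          seed = child_seed(seed, 100L + f)),
      error = function(e) NULL)
    prof <- if (is.null(fdr_f)) NULL else tryCatch(
      build_profiles(C[, train, drop = FALSE], labels[train], fdr_f,
                     max_features = max_features, fdr_cap = fdr_cap),
      error = function(e) NULL)
    if (is.null(prof)) {
      warning("fold ", f, ": no usable profile; skipped")
      next
    }
    pred <- predict(prof, C[, test, drop = FALSE],
                    min_overlap = min_overlap)
    truth_f <- as.integer(labels[test])
    scored <- if (is.null(core_mask)) rep(TRUE, length(test))
              else as.logical(core_mask[test])
    ok <- scored & !is.na(pred$cluster)
    n_correct <- n_correct + sum(pred$cluster[ok] == truth_f[ok])
    n_assigned <- n_assigned + sum(ok)
    n_held <- n_held + sum(scored)
    per_fold[[length(per_fold) + 1L]] <- data.frame(
      fold = f, n_test = sum(scored), n_assigned = sum(ok),
      n_correct = sum(pred$cluster[ok] == truth_f[ok]))
  }
  if (!n_assigned) stop("no patient could be assigned in any fold")
  list(accuracy = n_correct / n_assigned, n_correct = n_correct,
       n_assigned = n_assigned, n_held_out = n_held,
       per_fold = do.call(rbind, per_fold))
}
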