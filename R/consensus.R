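#' Cluster-set submissions
#'
#' A cluster set is one solver's partition of subjects into labeled
#' clusters, represented as a named character vector (names = subject
#' ids, values = opaque cluster labels).  A submission collection is a
#' named list of cluster sets.  The long CSV dialect has columns
#' `submission_id,subject_id,cluster_label`.
#'
#' @param path path to a submissions CSV.
#' @return a named list of named character vectors.
#' @export
read_submissions <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("submission_id", "subject_id", "cluster_label")
  if (!all(need %in% names(d)))
    stop(path, ": header must contain ", paste(need, collapse = ","))
  split_sets <- split(d, d$submission_id)
  lapply(split_sets, function(s)
    stats::setNames(s$cluster_label, s$subject_id))
}

#' @rdname read_submissions
#' @param submissions a named list of named character vectors.
#' @export
write_submissions <- function(submissions, path) {
  submissions <- as_submission_list(submissions)
  d <- do.call(rbind, lapply(names(submissions), function(id) {
    s <- submissions[[id]]
    data.frame(submission_id = id, subject_id = names(s),
               cluster_label = unname(s), stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

as_submission_list <- function(submissions) {
  if (is.data.frame(submissions)) {
    split_sets <- split(submissions, submissions$submission_id)
    return(lapply(split_sets, function(s)
      stats::setNames(as.character(s$cluster_label), s$subject_id)))
  }
  if (!is.list(submissions)) stop("submissions must be a list of cluster sets")
  if (is.null(names(submissions)))
    names(submissions) <- sprintf("submission%03d", seq_along(submissions))
  lapply(submissions, function(s) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      stop("each cluster set must be a named vector with unique subject ids")
    stats::setNames(as.character(s), names(s))
  })
}

#' Weighted co-clustering matrix
#'
#' Aggregates many cluster-set submissions into a symmetric
#' subject-by-subject matrix `M` whose entry for subjects `i`, `j` is the
#' sum over submissions that place them in the same cluster of
#' `log(p / c_s)`, where `p` is the total number of subjects and `c_s`
#' the size of the shared cluster (natural log).  Smaller shared clusters
#' thus carry more weight; a cluster containing all `p` subjects
#' contributes `log(1) = 0`.  The diagonal is 0 by convention.
#'
#' @param submissions a list of cluster sets (see [read_submissions()]).
#' @param subjects optional character vector fixing the subject universe
#'   and ordering; defaults to the sorted union of submission subjects.
#' @return a symmetric numeric matrix with subject ids as dimnames.
#' @examples
#' subs <- list(a = c(A = "x", B = "x", C = "y", D = "y"))
#' build_cocluster_matrix(subs)["A", "B"]  # log(4/2)
#' @export
build_cocluster_matrix <- function(submissions, subjects = NULL) {
  submissions <- as_submission_list(submissions)
  if (!length(submissions)) stop("at least one submission is required")
  if (is.null(subjects))
    subjects <- sort(unique(unlist(lapply(submissions, names))))
  subjects <- as.character(subjects)
  p <- length(subjects)
  M <- matrix(0, p, p, dimnames = list(subjects, subjects))
  for (s in submissions) {
    unknown <- setdiff(names(s), subjects)
    if (length(unknown))
      stop("submission contains unknown subject(s): ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    for (lab in unique(s)) {
      idx <- match(names(s)[s == lab], subjects)
      cs <- length(idx)
      if (cs >= 2L && cs < p)
        M[idx, idx] <- M[idx, idx] + log(p / cs)
      # cs == p contributes log(1) = 0; cs == 1 has no pairs
    }
  }
  diag(M) <- 0
  M
}

#' Permutation FDR for co-clustered patient pairs
#'
#' Assesses which pairs of subjects are co-clustered more strongly than
#' expected by chance.  For each of `n_perm` permutations, every
#' submission's subjects are randomly reassigned to clusters of the same
#' sizes as in the original submission and the co-clustering matrix is
#' recomputed.  The FDR at an observed pair score `m` is the SAM-style
#' ratio (mean per-permutation count of permuted scores >= m) / (count of
#' observed scores >= m), clipped to \[0, 1\] and made monotone
#' non-increasing in `m` by a running minimum from the strongest score
#' downwards.
#'
#' @param M co-clustering matrix from [build_cocluster_matrix()].
#' @param submissions the submissions that produced `M`.
#' @param n_perm number of permutations (>= 10; 100 in the full analysis).
#' @param seed integer seed.
#' @return an object of class `pair_fdr`: a data frame with columns
#'   `subject_i`, `subject_j`, `score`, `fdr`, one row per unordered pair.
#' @export
pair_fdr <- function(M, submissions, n_perm = 100L, seed = NULL) {
  if (n_perm < 10L) stop("n_perm must be at least 10")
  submissions <- as_submission_list(submissions)
  subjects <- rownames(M)
  p <- length(subjects)
  ut <- upper.tri(M)
  obs <- M[ut]
  perm_sorted <- with_seed(seed, {
    sort(unlist(lapply(seq_len(n_perm), function(b) {
      perm_subs <- lapply(submissions, function(s)
        stats::setNames(sample(unname(s)), names(s)))
      build_cocluster_matrix(perm_subs, subjects)[ut]
    }), use.names = FALSE))
  })
  obs_sorted <- sort(obs)
  n_perm_total <- length(perm_sorted)
  count_ge <- function(x, sorted_vals)
    length(sorted_vals) - findInterval(x, sorted_vals, left.open = TRUE)
  n_false <- count_ge(obs, perm_sorted) / n_perm
  n_true <- count_ge(obs, obs_sorted)
  raw <- pmin(pmax(n_false / n_true, 0), 1)
  # q-value convention: monotone non-increasing in the observed score
  ord <- order(obs)
  fdr <- numeric(length(obs))
  fdr[ord] <- cummin(raw[ord])
  ij <- which(ut, arr.ind = TRUE)
  out <- data.frame(subject_i = subjects[ij[, 1L]],
                    subject_j = subjects[ij[, 2L]],
                    score = obs, fdr = fdr, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  class(out) <- c("pair_fdr", "data.frame")
  out
}

#' Graph of significantly co-clustered pairs
#'
#' Builds an undirected graph whose edges are the subject pairs with FDR
#' at or below the threshold (5% in the original analysis).  Vertices are
#' the subjects incident to at least one significant edge; the graph can
#' be exported as DOT (for graphviz) or GraphML.
#'
#' @param fdr a `pair_fdr` object.
#' @param threshold FDR threshold (default 0.05).
#' @return an `igraph` graph with edge attributes `fdr` and `score`.
#' @export
significant_pair_graph <- function(fdr, threshold = 0.05) {
  stopifnot(inherits(fdr, "pair_fdr"))
  sig <- fdr[fdr$fdr <= threshold & fdr$score > 0, , drop = FALSE]
  igraph::graph_from_data_frame(
    sig[, c("subject_i", "subject_j", "fdr", "score")], directed = FALSE)
}

#' @rdname significant_pair_graph
#' @param graph an igraph graph.
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @export
write_pair_graph <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}

# Normalize matrix rows to zero mean / unit Euclidean norm so that
# tcrossprod gives Pearson correlations.  Constant rows map to zero
# vectors (correlation treated as 0, resolved by the tie-break rule).
row_standardize <- function(X) {
  ctr <- X - rowMeans(X)
  nrm <- sqrt(rowSums(ctr^2))
  nrm[nrm == 0] <- Inf
  ctr / nrm
}

#' k-means on the co-clustering matrix with correlation distance
#'
#' Clusters subjects by the rows of the co-clustering matrix `M` using
#' Lloyd iteration with distance `1 - Pearson correlation` between a
#' subject's row and a centroid, where each centroid is the arithmetic
#' mean of its members' rows.  The best of `n_restarts` random starts (by
#' total within-cluster distance) is returned.  Ties in assignment go to
#' the lowest cluster index; a subject with a constant row (undefined
#' correlation) is likewise assigned by the tie-break rule.  An empty
#' cluster is re-seeded from the subject farthest from its current
#' centroid.  Cluster labels are renumbered in order of first appearance
#' along the subject ordering, so the result is deterministic under a
#' fixed seed.
#'
#' @param M co-clustering matrix (subjects as rownames).
#' @param k number of clusters (1 <= k <= number of subjects).
#' @param seed integer seed.
#' @param n_restarts number of random restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @return a list with `k`, `labels` (named integer vector), `centroids`
#'   (k x p matrix of mean rows) and `within` (total within-cluster
#'   distance).
#' @export
consensus_kmeans <- function(M, k, seed = NULL, n_restarts = 10L,
                             max_iter = 100L) {
  p <- nrow(M)
  if (k < 1L || k > p) stop("k must be between 1 and the number of subjects")
  subjects <- rownames(M) %||% as.character(seq_len(p))
  X <- unname(as.matrix(M))
  Xn <- row_standardize(X)
  run_once <- function() {
    cent <- X[sample.int(p, k), , drop = FALSE]
    labels <- rep(0L, p)
    for (iter in seq_len(max_iter)) {
      S <- tcrossprod(Xn, row_standardize(cent))  # p x k correlations
      new_labels <- max.col(S, ties.method = "first")
      sizes <- tabulate(new_labels, nbins = k)
      for (c_empty in which(sizes == 0L)) {
        own <- S[cbind(seq_len(p), new_labels)]
        far <- which.min(own)  # farthest from its centroid
        new_labels[far] <- c_empty
        S[far, ] <- -Inf; S[far, c_empty] <- Inf
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      cent <- rowsum(X, labels) / tabulate(labels, nbins = k)
    }
    S <- tcrossprod(Xn, row_standardize(cent))
    within <- sum(1 - S[cbind(seq_len(p), labels)])
    list(labels = labels, within = within)
  }
  best <- with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(r) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "within"))]]
  })
  # canonical label order: by first appearance along the subject ordering
  u <- unique(best$labels)
  if (length(u) < k)  # a cluster emptied on the final update
    stop("k-means produced fewer than k non-empty clusters; reduce k")
  remap_inv <- integer(k)
  remap_inv[u] <- seq_along(u)
  labels <- remap_inv[best$labels]
  centroids <- rowsum(X, labels) / tabulate(labels, nbins = k)
  rownames(centroids) <- seq_len(k)
  colnames(centroids) <- subjects
  list(k = as.integer(k),
       labels = stats::setNames(as.integer(labels), subjects),
       centroids = centroids, within = best$within)
}

#' Core patients of each consensus cluster
#'
#' Within each cluster, subjects are ranked by correlation distance to
#' their cluster centroid and the closest half (ceiling of size/2) are
#' flagged as core; ties are broken by subject order.
#'
#' @param M co-clustering matrix.
#' @param labels named integer cluster labels.
#' @param centroids k x p centroid matrix (mean member rows).
#' @return named logical vector, `TRUE` for core patients.
#' @export
core_patients <- function(M, labels, centroids) {
  X <- unname(as.matrix(M))
  Xn <- row_standardize(X)
  Cn <- row_standardize(unname(as.matrix(centroids)))
  S <- tcrossprod(Xn, Cn)
  d <- 1 - S[cbind(seq_along(labels), as.integer(labels))]
  core <- logical(length(labels))
  for (c_id in sort(unique(as.integer(labels)))) {
    members <- which(as.integer(labels) == c_id)
    n_core <- ceiling(length(members) / 2)
    ord <- members[order(d[members])]  # stable: ties by subject order
    core[ord[seq_len(n_core)]] <- TRUE
  }
  stats::setNames(core, names(labels))
}

#' Consensus clustering of solver submissions
#'
#' Fits the full consensus-clustering model: builds the size-weighted
#' co-clustering matrix from the submissions, estimates per-pair
#' permutation FDRs and the significant-pair graph, partitions subjects
#' by correlation-distance k-means on the matrix rows, and flags the core
#' half of each cluster.  `k` is a required user choice; see
#' [suggest_k()] for decision support.
#'
#' @param submissions a list of cluster sets or a long data frame (see
#'   [read_submissions()]).
#' @param k number of consensus clusters.
#' @param subjects optional subject universe/ordering.
#' @param n_perm permutations for the pair FDR (>= 10).
#' @param fdr_threshold edge threshold for the significant-pair graph.
#' @param compute_fdr set `FALSE` to skip the (costly) permutation FDR.
#' @param seed integer seed.
#' @param n_restarts k-means restarts.
#' @return an object of class `consensus_clusters` with components
#'   `labels`, `centroids`, `core`, `M`, `pair_fdr`, `graph`, `within`.
#' @export
consensus_clusters <- function(submissions, k, subjects = NULL,
                               n_perm = 100L, fdr_threshold = 0.05,
                               compute_fdr = TRUE, seed = NULL,
                               n_restarts = 10L) {
  submissions <- as_submission_list(submissions)
  M <- build_cocluster_matrix(submissions, subjects)
  pf <- NULL; graph <- NULL
  if (compute_fdr) {
    pf <- pair_fdr(M, submissions, n_perm = n_perm,
                   seed = child_seed(seed, 7L))
    graph <- significant_pair_graph(pf, fdr_threshold)
  }
  km <- consensus_kmeans(M, k, seed = child_seed(seed, 11L),
                         n_restarts = n_restarts)
  core <- core_patients(M, km$labels, km$centroids)
  structure(list(k = km$k, labels = km$labels, centroids = km$centroids,
                 core = core, M = M, pair_fdr = pf, graph = graph,
                 within = km$within, n_submissions = length(submissions),
                 fdr_threshold = fdr_threshold,
                 call = match.call()),
            class = "consensus_clusters")
}

#' @export
print.consensus_clusters <- function(x, ...) {
  cat("Consensus clustering of", length(x$labels), "subjects from",
      x$n_submissions, "submissions\n")
  cat("k =", x$k, "; cluster sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  if (!is.null(x$graph))
    cat("significant pairs (FDR <=", x$fdr_threshold, "):",
        igraph::ecount(x$graph), "\n")
  invisible(x)
}

#' @export
summary.consensus_clusters <- function(object, ...) {
  sizes <- tabulate(object$labels, object$k)
  core_sizes <- vapply(seq_len(object$k), function(c_id)
    sum(object$core[object$labels == c_id]), integer(1))
  out <- data.frame(cluster = seq_len(object$k), size = sizes,
                    core = core_sizes)
  cat("Consensus clusters (within-cluster distance ",
      format(object$within, digits = 5), "):\n", sep = "")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.consensus_clusters <- function(x, ...) {
  ord <- order(x$labels)
  graphics::image(x$M[ord, ord], axes = FALSE, useRaster = TRUE,
        main = "Co-clustering matrix (subjects ordered by consensus cluster)",
        ...)
  invisible(x)
}

#' Diagnostics for choosing the number of consensus clusters
#'
#' The number of clusters was chosen visually in the original analysis;
#' this helper returns decision support only: the number of connected
#' components of the significant-pair graph and, for each candidate `k`,
#' the mean silhouette width under correlation distance between rows of
#' `M`.  No automatic choice is made.
#'
#' @param M co-clustering matrix.
#' @param graph optional significant-pair graph (component count is 0
#'   when `NULL` or edgeless).
#' @param k_range candidate values of k.
#' @param seed integer seed.
#' @param n_restarts k-means restarts per candidate.
#' @return a list with `components` and a data frame `per_k`
#'   (`k`, `mean_silhouette`).
#' @export
suggest_k <- function(M, graph = NULL, k_range = 2:8, seed = NULL,
                      n_restarts = 5L) {
  comp <- if (is.null(graph) || igraph::ecount(graph) == 0L) 0L
          else igraph::components(graph)$no
  D <- 1 - stats::cor(t(M))
  D[is.na(D)] <- 1
  diag(D) <- 0
  k_range <- k_range[k_range >= 2L & k_range <= nrow(M) - 1L]
  sil <- vapply(k_range, function(k) {
    km <- consensus_kmeans(M, k, seed = child_seed(seed, k),
                           n_restarts = n_restarts)
    if (requireNamespace("cluster", quietly = TRUE)) {
      s <- cluster::silhouette(as.integer(km$labels), dmatrix = D)
      mean(s[, "sil_width"])
    } else {
      mean_silhouette(as.integer(km$labels), D)
    }
  }, numeric(1))
  list(components = comp,
       per_k = data.frame(k = k_range, mean_silhouette = sil))
}

# Fallback silhouette (identical definition to cluster::silhouette).
mean_silhouette <- function(labels, D) {
  n <- length(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) <= 1L) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(c_id)
      mean(D[i, labels == c_id]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
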