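test_that("co-clustering weights follow log(p / cluster size)", {
  subs <- list(one = c(A = "x", B = "x", C = "y", D = "y"))
  M <- build_cocluster_matrix(subs)
  expect_equal(M["A", "B"], log(2))
  expect_equal(M["A", "C"], 0)
  expect_equal(diag(M), stats::setNames(rep(0, 4), LETTERS[1:4]))
  # the trivial all-in-one cluster carries zero weight
  allin <- list(one = stats::setNames(rep("z", 4), LETTERS[1:4]))
  expect_true(all(build_cocluster_matrix(allin) == 0))
  both <- build_cocluster_matrix(c(subs, allin))
  expect_equal(both, M)
})

test_that("co-clustering matrix equals the triple-loop oracle", {
  set.seed(51)
  for (rep in 1:20) {
    p <- sample(4:12, 1)
    subjects <- sprintf("P%02d", seq_len(p))
    subs <- random_submissions(sample(1:6, 1), subjects,
                               k = sample(2:4, 1))
    expect_equal(build_cocluster_matrix(subs, subjects),
                 m_oracle(subs, subjects))
  }
})

test_that("M is invariant to submission order and label renaming", {
  set.seed(52)
  subjects <- sprintf("P%02d", 1:8)
  subs <- random_submissions(5, subjects)
  M1 <- build_cocluster_matrix(subs, subjects)
  M2 <- build_cocluster_matrix(rev(subs), subjects)
  expect_equal(M1, M2)
  renamed <- lapply(subs, function(s)
    stats::setNames(paste0("renamed_", s), names(s)))
  expect_equal(build_cocluster_matrix(renamed, subjects), M1)
  bad <- list(c(ZZZ = "c1"))
  expect_error(build_cocluster_matrix(bad, subjects), "unknown subject")
})

test_that("pair FDR separates planted from chance co-clustering", {
  subjects <- sprintf("P%02d", 1:24)
  truth <- stats::setNames(rep(1:4, each = 6), subjects)
  identical_subs <- lapply(1:8, function(i)
    stats::setNames(paste0("c", truth), subjects))
  M <- build_cocluster_matrix(identical_subs, subjects)
  pf <- pair_fdr(M, identical_subs, n_perm = 50, seed = 61)
  within <- truth[pf$subject_i] == truth[pf$subject_j]
  expect_true(all(pf$fdr[within] < 0.05))
  expect_true(all(pf$fdr[!within] >= 0.05))
  # maximal observed score never reached by permutation scores -> FDR 0
  expect_equal(min(pf$fdr[within]), 0)
  # FDR is monotone non-increasing in the observed score
  ord <- order(pf$score)
  expect_true(all(diff(pf$fdr[ord]) <= 1e-12))
})

test_that("the significant-pair graph exports and round-trips", {
  subjects <- sprintf("P%02d", 1:12)
  truth <- stats::setNames(rep(1:2, each = 6), subjects)
  subs <- lapply(1:6, function(i) stats::setNames(paste0("c", truth), subjects))
  M <- build_cocluster_matrix(subs, subjects)
  pf <- pair_fdr(M, subs, n_perm = 30, seed = 62)
  g <- significant_pair_graph(pf, threshold = 0.05)
  expect_s3_class(g, "igraph")
  edge_set <- function(gr) {
    e <- igraph::as_edgelist(gr)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_pair_graph(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(edge_set(back), edge_set(g))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_pair_graph(g, dot, "dot")
  expect_true(file.size(dot) > 0)
  # threshold 1 keeps every scored pair with positive evidence
  g_all <- significant_pair_graph(pf, threshold = 1)
  expect_equal(igraph::ecount(g_all), sum(pf$score > 0))
  # no significant pairs -> empty graph
  pf0 <- pf; pf0$fdr <- 1
  class(pf0) <- class(pf)
  expect_equal(igraph::ecount(significant_pair_graph(pf0, 0.05)), 0)
})

test_that("correlation k-means recovers planted blocks and handles edge cases", {
  set.seed(63)
  p <- 40
  subjects <- sprintf("P%02d", 1:p)
  truth <- rep(1:2, each = p / 2)
  M <- matrix(rnorm(p * p, 0, 0.05), p, p, dimnames = list(subjects, subjects))
  M[truth == 1, truth == 1] <- M[truth == 1, truth == 1] + 2
  M[truth == 2, truth == 2] <- M[truth == 2, truth == 2] + 2
  M <- (M + t(M)) / 2; diag(M) <- 0
  km <- consensus_kmeans(M, k = 2, seed = 64)
  expect_equal(length(unique(km$labels[truth == 1])), 1)
  expect_equal(length(unique(km$labels[truth == 2])), 1)
  expect_false(km$labels[1] == km$labels[p])
  # k = 1 puts everyone together
  km1 <- consensus_kmeans(M, k = 1, seed = 65)
  expect_true(all(km1$labels == 1))
  # duplicated rows always share a label
  M2 <- M; M2[2, ] <- M2[1, ]; M2[, 2] <- M2[, 1]; diag(M2) <- 0
  km2 <- consensus_kmeans(M2, k = 2, seed = 66)
  expect_equal(unname(km2$labels[1]), unname(km2$labels[2]))
  # determinism under a fixed seed
  expect_identical(consensus_kmeans(M, 2, seed = 67),
                   consensus_kmeans(M, 2, seed = 67))
})

test_that("consensus labels are invariant (up to renaming) to subject order", {
  set.seed(68)
  subjects <- sprintf("P%02d", 1:20)
  truth <- stats::setNames(rep(1:2, each = 10), subjects)
  subs <- lapply(1:10, function(i) {
    lab <- truth
    flip <- sample(20, 2)
    lab[flip] <- sample(1:2, 2, replace = TRUE)
    stats::setNames(paste0("c", lab), subjects)
  })
  M1 <- build_cocluster_matrix(subs, subjects)
  M2 <- build_cocluster_matrix(subs, rev(subjects))
  km1 <- consensus_kmeans(M1, 2, seed = 69)
  km2 <- consensus_kmeans(M2, 2, seed = 69)
  agree <- table(km1$labels[subjects], km2$labels[subjects])
  expect_equal(sum(apply(agree, 1, max)), 20)  # identical partition
})

test_that("core patients are the nearest half of each cluster", {
  subjects <- sprintf("P%02d", 1:12)
  truth <- rep(1:2, each = 6)
  M <- matrix(0, 12, 12, dimnames = list(subjects, subjects))
  M[truth == 1, truth == 1] <- 3
  M[truth == 2, truth == 2] <- 3
  # make P06 an outlier within cluster 1
  M[6, ] <- rnorm(12, 0, 0.1); M[, 6] <- M[6, ]
  M <- (M + t(M)) / 2; diag(M) <- 0
  km <- consensus_kmeans(M, 2, seed = 71)
  core <- core_patients(M, km$labels, km$centroids)
  for (c_id in 1:2) {
    members <- km$labels == c_id
    expect_equal(sum(core[members]), ceiling(sum(members) / 2))
  }
  if (km$labels["P06"] == km$labels["P01"])  # outlier is never core
    expect_false(core[["P06"]])
  # two identical rows: exactly one core member, tie to subject order
  Ms <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(Ms) <- 0
  kms <- consensus_kmeans(Ms, 1, seed = 72)
  cs <- core_patients(Ms, kms$labels, kms$centroids)
  expect_equal(unname(cs), c(TRUE, FALSE))
})

test_that("suggest_k reports graph components and a silhouette peak", {
  set.seed(73)
  p <- 48
  subjects <- sprintf("P%02d", 1:p)
  truth <- stats::setNames(rep(1:4, each = p / 4), subjects)
  subs <- lapply(1:10, function(i) stats::setNames(paste0("c", truth), subjects))
  M <- build_cocluster_matrix(subs, subjects)
  pf <- pair_fdr(M, subs, n_perm = 30, seed = 74)
  g <- significant_pair_graph(pf)
  diag_out <- suggest_k(M, g, k_range = 2:6, seed = 75)
  expect_equal(diag_out$components, 4)
  best <- diag_out$per_k$k[which.max(diag_out$per_k$mean_silhouette)]
  expect_equal(best, 4)
  expect_equal(suggest_k(M, NULL, k_range = 2:3, seed = 76)$components, 0)
})

test_that("the consensus_clusters fit exposes labels, core mask and graph", {
  set.seed(77)
  subjects <- sprintf("P%02d", 1:30)
  truth <- stats::setNames(rep(1:3, each = 10), subjects)
  subs <- lapply(1:12, function(i) {
    lab <- truth
    flip <- sample(30, 3)
    lab[flip] <- sample(1:3, 3, replace = TRUE)
    stats::setNames(paste0("c", lab), subjects)
  })
  fit <- consensus_clusters(subs, k = 3, n_perm = 20, seed = 78)
  expect_s3_class(fit, "consensus_clusters")
  expect_equal(sort(unique(unname(fit$labels))), 1:3)
  expect_equal(sum(fit$core),
               sum(ceiling(table(fit$labels) / 2)))
  expect_output(print(fit), "Consensus clustering")
  s <- summary(fit)
  expect_equal(sum(s$size), 30)
})
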