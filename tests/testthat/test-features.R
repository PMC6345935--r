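test_that("longitudinal summaries match a per-subject loop oracle", {
  dict <- feature_dictionary(c("score", "site"), c("continuous", "discrete"))
  tab <- make_table("s1", "score", c(1, 2, 3), c(0, 30, 60))
  fs <- summarize_features(tab, dict)
  expect_equal(unname(fs$C["score.mean", "s1"]), 2)
  expect_equal(unname(fs$C["score.min", "s1"]), 1)
  expect_equal(unname(fs$C["score.max", "s1"]), 3)
  single <- summarize_features(make_table("s1", "score", 5, 10), dict)
  expect_equal(unname(single$C[, "s1"]), c(5, 5, 5))

  set.seed(81)
  n <- 200
  tab <- make_table(sample(sprintf("s%02d", 1:10), n, TRUE),
                    sample(c("score", "site"), n, TRUE),
                    as.character(sample(1:5, n, TRUE)),
                    sample(0:400, n, TRUE))
  tab$value[tab$feature_name == "site"] <-
    sample(c("bulbar", "limb"), sum(tab$feature_name == "site"), TRUE)
  fs <- summarize_features(tab, dict, window = observation_window())
  for (s in colnames(fs$C)) {
    v <- as.numeric(tab$value[tab$subject_id == s &
                                tab$feature_name == "score" &
                                tab$delta_days <= 91 & tab$delta_days >= 0])
    if (!length(v)) {
      expect_true(is.na(fs$C["score.mean", s]))
    } else {
      expect_equal(unname(fs$C["score.mean", s]), mean(v))
      expect_equal(unname(fs$C["score.min", s]), min(v))
      expect_equal(unname(fs$C["score.max", s]), max(v))
    }
    d <- tab$value[tab$subject_id == s & tab$feature_name == "site" &
                     tab$delta_days <= 91 & tab$delta_days >= 0]
    if (length(d)) {
      counts <- table(d)
      expect_true(fs$D["site", s] %in%
                    names(counts)[counts == max(counts)])
    }
  }
})

test_that("the ANOVA statistic matches lm/aov and the t-squared identity", {
  set.seed(82)
  for (rep in 1:10) {
    g <- sample(1:3, 40, replace = TRUE)
    v <- rnorm(40) + g / 2
    v[sample(40, 4)] <- NA
    f_ref <- stats::anova(stats::lm(v ~ factor(g)))$`F value`[1]
    expect_equal(anova_statistic(v, g), f_ref)
  }
  g2 <- rep(1:2, each = 15)
  v2 <- rnorm(30) + g2
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(anova_statistic(v2, g2), unname(tt$statistic^2))
  expect_equal(anova_statistic(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3)), 0)
  expect_true(is.na(anova_statistic(c(1, 2, 3), c(1, 1, 1))))
})

test_that("the Fisher statistic reproduces exact hypergeometric p-values", {
  v <- rep(c("a", "b"), each = 5)
  g <- rep(1:2, times = 5)[order(rep(1:2, times = 5))]
  # 2x2 table [[5,0],[0,5]] via direct construction
  v <- c(rep("a", 5), rep("b", 5))
  g <- c(rep(1, 5), rep(2, 5))
  expect_equal(fisher_statistic(v, g), 2 / choose(10, 5))
  # symmetric swap leaves p unchanged
  expect_equal(fisher_statistic(v, 3 - g), fisher_statistic(v, g))
  # independent margins give a large p
  set.seed(83)
  v2 <- sample(c("a", "b"), 400, TRUE)
  g2 <- sample(1:2, 400, TRUE)
  expect_gt(fisher_statistic(v2, g2), 0.05)
  expect_true(is.na(fisher_statistic(rep("a", 10), rep(1:2, 5))))
})

test_that("integrated rank FDR finds a planted row and stays calibrated", {
  set.seed(84)
  pl <- planted_C(n = 120, k = 3, n_diff = 1, n_null = 50, effect = 2)
  res <- integrated_rank_fdr(pl$C, g = pl$g, n_perm = 50, seed = 85)
  tab <- res$table
  expect_lt(tab$fdr[tab$feature == pl$diff], 0.05)
  expect_gt(stats::median(tab$fdr[tab$feature %in% pl$null]), 0.5)
  # determinism: identical seed gives bit-identical tables
  res2 <- integrated_rank_fdr(pl$C, g = pl$g, n_perm = 50, seed = 85)
  expect_identical(res$table, res2$table)
  # FDR monotone non-increasing in the rank
  ord <- order(tab$rank)
  expect_true(all(diff(tab$fdr[ord]) <= 1e-12))
})

test_that("a shuffled design yields near-nominal false positive rates", {
  set.seed(86)
  fractions <- vapply(1:10, function(rep) {
    pl <- planted_C(n = 90, k = 3, n_diff = 0, n_null = 40, effect = 0)
    res <- integrated_rank_fdr(pl$C, g = pl$g, n_perm = 30,
                               seed = 860 + rep)
    mean(res$table$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(fractions), 0.08)
})

test_that("discrete and continuous families integrate into one FDR table", {
  set.seed(87)
  pl <- planted_C(n = 120, k = 2, n_diff = 1, n_null = 10, effect = 2)
  D <- matrix(NA_character_, 2, 120,
              dimnames = list(c("site", "noise_cat"), pl$subjects))
  D["site", ] <- ifelse(pl$g == 1,
                        sample(c("bulbar", "limb"), 120, TRUE, c(0.8, 0.2)),
                        sample(c("bulbar", "limb"), 120, TRUE, c(0.2, 0.8)))
  D["noise_cat", ] <- sample(c("x", "y", "z"), 120, TRUE)
  res <- integrated_rank_fdr(pl$C, D, g = pl$g, n_perm = 40, seed = 88)
  expect_setequal(unique(res$table$family), c("continuous", "discrete"))
  expect_lt(res$table$fdr[res$table$feature == "site"], 0.05)
  expect_gt(res$table$fdr[res$table$feature == "noise_cat"], 0.05)
  # continuous-only input works too
  res_c <- integrated_rank_fdr(pl$C, NULL, g = pl$g, n_perm = 40, seed = 88)
  expect_true(all(res_c$table$family == "continuous"))
})

test_that("pairwise t-tests are gated by global significance and directed", {
  set.seed(89)
  n <- 150
  g <- stats::setNames(rep(1:3, each = 50), sprintf("P%03d", 1:n))
  C <- rbind(hot = rnorm(n), cold = rnorm(n))
  colnames(C) <- names(g)
  C["hot", g == 1] <- C["hot", g == 1] + 3   # cluster 1 clearly higher
  res <- integrated_rank_fdr(C, g = g, n_perm = 50, seed = 90)
  pw <- pairwise_ttest_fdr(C, g, res)
  expect_true(all(pw$feature == "hot"))      # "cold" is not gated
  sig12 <- pw[pw$cluster_a == 1 & pw$cluster_b == 2, ]
  expect_true(sig12$significant)
  expect_equal(sig12$direction, 1)
  sig23 <- pw[pw$cluster_a == 2 & pw$cluster_b == 3, ]
  expect_false(isTRUE(sig23$significant))
})

test_that("the heatmap counting rule and [-1, 1] scaling match hand values", {
  pw <- data.frame(
    feature = "f1",
    cluster_a = c(1, 1, 2), cluster_b = c(2, 3, 3),
    t = c(5, 5, 0), fdr = c(0.001, 0.001, 0.9),
    direction = c(1, 1, 2), significant = c(TRUE, TRUE, FALSE))
  class(pw) <- c("pairwise_fdr", "data.frame")
  H <- heatmap_matrix(pw, clusters = 1:3)
  expect_equal(unname(H["f1", ]), c(1, -1, -1))  # raw ranks (2, -1, -1)
  # no significant pair -> all-zero row
  pw0 <- pw; pw0$significant <- FALSE
  class(pw0) <- c("pairwise_fdr", "data.frame")
  expect_equal(unname(heatmap_matrix(pw0, clusters = 1:3)["f1", ]),
               c(0, 0, 0))
  # k = 2 single significant pair
  pw2 <- pw[1, ]; class(pw2) <- c("pairwise_fdr", "data.frame")
  expect_equal(unname(heatmap_matrix(pw2, clusters = 1:2)["f1", ]),
               c(1, -1))
})

test_that("feature usage tallies selection probabilities", {
  lists <- list(c("age", "alsfrs"), c("age", "fvc"), c("age"),
                c("alsfrs", "fvc"))
  tal <- feature_usage_tally(lists)
  expect_equal(tal$probability[tal$feature == "age"], 0.75)
  expect_equal(tal$probability[tal$feature == "fvc"], 0.5)
  grp <- feature_usage_tally(lists, subchallenge = c(1, 1, 2, 2))
  expect_equal(grp$average[grp$feature == "age"], mean(c(1, 0.5)))
  expect_error(feature_usage_tally(list(letters[1:7])), "more than 6")
})
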