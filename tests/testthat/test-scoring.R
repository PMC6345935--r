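test_that("rmsd and pearson match direct formulas and reject mismatches", {
  t0 <- stats::setNames(c(-1, -0.5, 0.2, -2), paste0("s", 1:4))
  expect_equal(rmsd(t0, t0), 0)
  expect_equal(rmsd(t0 + 1, t0), 1)
  expect_equal(pearson_cc(t0, t0), 1)
  expect_equal(pearson_cc(-t0, t0), -1)
  set.seed(11)
  p <- stats::setNames(rnorm(20), paste0("s", 1:20))
  a <- stats::setNames(rnorm(20), paste0("s", 1:20))
  expect_equal(rmsd(p, a), sqrt(sum((p - a)^2) / 20))
  expect_equal(pearson_cc(p, a),
               sum((p - mean(p)) * (a - mean(a))) /
                 sqrt(sum((p - mean(p))^2) * sum((a - mean(a))^2)))
  expect_error(rmsd(p, a[1:10]), "different subject sets")
  expect_error(pearson_cc(stats::setNames(rep(1, 20), names(a)), a),
               "constant")
})

test_that("concordance index reproduces the printed pair rule", {
  expect_equal(concordance_index(c(0.1, 0.2, 0.3), c(1, 2, 3)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(2, 1, 3)), 2 / 3)
  # single censored-then-event pair is incomparable
  expect_error(concordance_index(c(1, 2), c(1, 2), events = c(FALSE, TRUE)),
               "no comparable pairs")
  # reversed: the smaller time is an event, so the pair is comparable
  expect_equal(concordance_index(c(1, 2), c(1, 2), events = c(TRUE, FALSE)),
               1)
})

test_that("concordance index equals the brute-force oracle with and without censoring", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(3:50, 1)
    actual <- sample(1:25, n, replace = TRUE)       # forces ties
    pred <- round(runif(n), 1)                      # forces prediction ties
    events <- if (rep %% 2) sample(c(TRUE, FALSE), n, replace = TRUE)
    expected <- ci_oracle(pred, actual, events)
    if (is.na(expected)) {
      expect_error(concordance_index(pred, actual, events), "comparable")
    } else {
      expect_equal(concordance_index(pred, actual, events), expected)
    }
  }
})

test_that("tie-free CI is antisymmetric under prediction negation", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    actual <- sample(seq_len(200), n)   # distinct
    pred <- runif(n)
    expect_equal(concordance_index(pred, actual) +
                   concordance_index(-pred, actual), 1)
  }
})

test_that("CI agrees with the survival package on tie-free uncensored data", {
  skip_if_not_installed("survival")
  set.seed(5)
  n <- 40
  actual <- sample(1:1000, n)
  pred <- runif(n)
  fit <- survival::concordance(survival::Surv(actual, rep(1, n)) ~ pred)
  expect_equal(concordance_index(pred, actual), unname(fit$concordance))
})

test_that("metrics are invariant to subject ordering", {
  set.seed(13)
  p <- stats::setNames(rnorm(15), paste0("s", 1:15))
  a <- stats::setNames(rnorm(15), paste0("s", 1:15))
  shuf <- sample(names(p))
  expect_equal(rmsd(p[shuf], a), rmsd(p, a))
  expect_equal(pearson_cc(p[shuf], a), pearson_cc(p, a))
})

test_that("permutation null is reproducible and centers the CI at 1/2", {
  set.seed(17)
  p <- stats::setNames(rnorm(30), paste0("s", 1:30))
  a <- stats::setNames(rnorm(30), paste0("s", 1:30))
  n1 <- permutation_null(rmsd, p, a, n_perm = 300, seed = 42)
  n2 <- permutation_null(rmsd, p, a, n_perm = 300, seed = 42)
  expect_identical(n1, n2)
  ci_null <- permutation_null(function(pr, tr) concordance_index(pr, tr),
                              p, a, n_perm = 1000, seed = 43)
  expect_lt(abs(ci_null$mean - 0.5), 3 * ci_null$sd / sqrt(1000))
  expect_error(permutation_null(rmsd, p, a, n_perm = 10), "at least 100")
})

test_that("score reports obey the z-combination identities", {
  set.seed(23)
  truth <- stats::setNames(rnorm(40, -0.7, 0.4), sprintf("s%02d", 1:40))
  pred <- truth + rnorm(40, 0, 0.1)
  rep1 <- score_slope(pred, truth, n_perm = 400, seed = 3)
  expect_equal(rep1$combined,
               unname(rep1$z["ci"] + rep1$z["pcc"] - rep1$z["rmsd"]))
  expect_equal(unname(rep1$z),
               unname((rep1$metrics - rep1$null_mean) / rep1$null_sd))
  expect_gt(rep1$combined, 3)  # near-perfect predictions score high

  sv_truth <- data.frame(subject_id = sprintf("s%02d", 1:40),
                         time_days = sample(100:900, 40),
                         event = sample(c(TRUE, FALSE), 40, TRUE))
  risk <- rank(sv_truth$time_days) / 40
  sv_pred <- data.frame(subject_id = sv_truth$subject_id,
                        p12 = risk, p18 = risk, p24 = risk)
  rep2 <- score_survival(sv_pred, sv_truth, n_perm = 400, seed = 4)
  expect_equal(rep2$combined, unname(sum(rep2$z)))
  expect_gt(rep2$combined, 3)
})

test_that("bootstrap comparison detects dominance and respects symmetry", {
  set.seed(29)
  truth <- stats::setNames(rnorm(50, -0.7, 0.4), sprintf("s%02d", 1:50))
  good <- truth
  bad <- stats::setNames(sample(truth), names(truth))
  bt <- bootstrap_compare(good, bad, truth, kind = "slope",
                          n_boot = 200, n_perm = 300, seed = 7)
  expect_gte(as.numeric(bt), 95)
  bt_same <- bootstrap_compare(good, good, truth, kind = "slope",
                               n_boot = 100, n_perm = 200, seed = 8)
  expect_equal(as.numeric(bt_same), 0)  # never *strictly* greater than itself
  bt_rep <- bootstrap_compare(good, bad, truth, kind = "slope",
                              n_boot = 50, n_perm = 200, seed = 9)
  bt_rep2 <- bootstrap_compare(good, bad, truth, kind = "slope",
                               n_boot = 50, n_perm = 200, seed = 9)
  expect_identical(bt_rep, bt_rep2)
})
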