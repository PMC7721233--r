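test_that("leave-one-run-out folds partition the runs", {
  f8 <- leave_one_run_out_folds(rep(1:8, each = 6))
  expect_equal(nrow(f8), 8)
  expect_equal(f8$test_run, 1:8)
  expect_true(all(vapply(seq_len(8),
                         function(i) !f8$test_run[i] %in% f8$train_runs[[i]],
                         logical(1))))
  expect_setequal(unlist(f8$train_runs), 1:8)
  f2 <- leave_one_run_out_folds(c(1, 1, 2, 2))
  expect_equal(nrow(f2), 2)
  expect_error(leave_one_run_out_folds(rep(1, 10)), "two runs")
})

test_that("the linear classifier separates separable clouds and is
           deterministic", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
    y <- rep(c("A", "B"), each = 20)
  })
  clf <- train_linear_classifier(x, y)
  expect_equal(mean(predict(clf, x) == y), 1)
  clf2 <- train_linear_classifier(x, y)
  expect_identical(clf$w, clf2$w)
  expect_identical(clf$b, clf2$b)
  expect_error(train_linear_classifier(x, rep("A", 40)), "two classes")
})

test_that("decision values are oriented so positive means the first sorted
           label, with ties going first", {
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(20, 2), 10), matrix(rnorm(20, -2), 10))
  })
  # train with labels in both orders; orientation must not depend on it
  for (y in list(rep(c("CP", "NM"), each = 10), rep(c("NM", "CP"), each = 10))) {
    clf <- train_linear_classifier(x, y)
    d <- decision_values(clf, x)
    expect_equal(unique(predict(clf, x)[d > 0]), "CP")
  }
})

test_that("pairwise discrimination is perfect without noise and at chance
           without signal", {
  means <- condition_means(ip_dist = 50, cp_nm_dist = 50)
  bs <- synthetic_betas(means, n_blocks_per_cond = 8, n_runs = 4,
                        noise_sd = 0.01, seed = 5)
  res <- pairwise_discrimination(bs, c("IP", "CP"))
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$mean_accuracy, mean(res$folds$accuracy))
  expect_equal(sum(res$confusion), sum(bs$condition %in% c("IP", "CP")))

  null_means <- condition_means(ip_dist = 0, cp_nm_dist = 0)
  accs <- vapply(1:10, function(i) {
    bs0 <- synthetic_betas(null_means, n_blocks_per_cond = 12, n_runs = 4,
                           noise_sd = 1, seed = 100 + i)
    pairwise_discrimination(bs0, c("CP", "NM"))$mean_accuracy
  }, numeric(1))
  # 96 test blocks per dataset; mean of 10 runs should sit near 0.5
  expect_gt(mean(accs), 0.38)
  expect_lt(mean(accs), 0.62)
})

test_that("a run missing one condition is reported by name", {
  means <- condition_means()
  bs <- synthetic_betas(means, n_blocks_per_cond = 4, n_runs = 4, seed = 6)
  drop <- !(bs$condition == "CP" & bs$run == 3)
  sub <- structure(bs[drop, ], class = class(bs),
                   voxel_cols = attr(bs, "voxel_cols"))
  expect_error(pairwise_discrimination(sub, c("IP", "CP")), "run 3")
})

test_that("cross-decoding absorbs a condition into its lookalike class", {
  # NM identical in distribution to CP, both far from IP
  means <- condition_means(ip_dist = 30, cp_nm_dist = 0)
  bs <- synthetic_betas(means, n_blocks_per_cond = 8, n_runs = 4,
                        noise_sd = 0.5, seed = 7)
  res <- cross_decode(bs, trained_pair = c("IP", "CP"), tested = "NM")
  expect_equal(sum(res$fraction_labeled), 1)
  expect_gt(res$fraction_labeled[["CP"]], 0.95)
})

test_that("cross-decoding of an equidistant condition is near symmetric", {
  # NM orthogonal to the IP-CP axis and equidistant from both
  withr::with_seed(8, {
    u <- rnorm(12); u <- u / sqrt(sum(u^2))
    v <- rnorm(12); v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
    means <- cbind(IP = 3 * u, CP = -3 * u, NM = 3 * v)
  })
  fracs <- vapply(1:5, function(i) {
    bs <- synthetic_betas(means, n_blocks_per_cond = 12, n_runs = 4,
                          noise_sd = 1, seed = 200 + i)
    cross_decode(bs, c("IP", "CP"), "NM")$fraction_labeled[["IP"]]
  }, numeric(1))
  expect_gt(mean(fracs), 0.3)
  expect_lt(mean(fracs), 0.7)
})

test_that("testing a trained condition is a usage error", {
  bs <- synthetic_betas(condition_means(), seed = 9)
  expect_error(cross_decode(bs, c("IP", "CP"), "CP"), "untrained|trained")
})
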