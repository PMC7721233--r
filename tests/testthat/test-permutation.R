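test_that("permutations preserve per-run label counts", {
  labels <- rep(rep(c("IP", "CP", "NM"), each = 2), 3)
  runs <- rep(1:3, each = 6)
  sch <- generate_permutations(labels, runs, n = 50, seed = 1)
  for (i in c(1, 25, 50)) {
    perm <- apply_permutation(sch, i)
    for (r in 1:3) {
      expect_equal(table(perm[runs == r]), table(labels[runs == r]))
    }
  }
  # slots never move across runs
  for (i in 1:50) {
    expect_equal(runs[sch$perms[i, ]], runs)
  }
})

test_that("schemes are seed-reproducible", {
  labels <- rep(c("CP", "NM"), 4)
  runs <- rep(1:2, each = 4)
  s1 <- generate_permutations(labels, runs, 20, seed = 3)
  s2 <- generate_permutations(labels, runs, 20, seed = 3)
  expect_identical(s1$perms, s2$perms)
  expect_error(generate_permutations(labels, runs, 0, seed = 1), "at least 1")
})

test_that("all balanced relabellings of a 2+2 run are reachable", {
  labels <- c("A", "A", "B", "B")
  runs <- rep(1, 4)
  sch <- generate_permutations(labels, runs, 10000, seed = 5)
  seen <- unique(apply(sch$perms, 1, function(ix) paste(labels[ix], collapse = "")))
  expect_equal(sort(seen), sort(unique(c(
    "AABB", "ABAB", "ABBA", "BAAB", "BABA", "BBAA"
  ))))
})

test_that("the add-one percentile rank rule gives the printed minimum p", {
  null_vals <- seq_len(15200)
  res <- permutation_p(null_vals, observed = 20000, tail = "one")
  expect_equal(res$p, 1 / 15201)
  expect_equal(signif(res$p, 2), 6.6e-5)
})

test_that("one- and two-tailed p-values follow the rank rule", {
  expect_equal(permutation_p(1:9, 10, "one")$p, 1 / 10)
  expect_equal(permutation_p(1:9, 5, "one")$p, (5 + 1) / 10)
  # two-tailed doubles the smaller tail, capped at 1
  expect_equal(permutation_p(1:9, 10, "two")$p, 2 / 10)
  expect_equal(permutation_p(1:9, 5, "two")$p, 1)
  # bounds
  expect_gte(permutation_p(rnorm(99), 100, "one")$p, 1 / 100)
  expect_lte(permutation_p(rnorm(99), -100, "one")$p, 1)
})

test_that("group nulls equal the participant average, checked by brute force", {
  means <- condition_means(ip_dist = 2)
  b1 <- synthetic_betas(means, n_blocks_per_cond = 4, n_runs = 2, seed = 11)
  b2 <- synthetic_betas(means, n_blocks_per_cond = 4, n_runs = 2, seed = 12)
  stat <- function(x, labels, runs) {
    mean(x[labels == "IP", 1]) - mean(x[labels == "CP", 1])
  }
  sch <- generate_permutations(b1$condition, b1$run, 25, seed = 13)
  gt <- group_permutation_test(list(b1, b2), stat, sch)
  for (i in c(1, 10, 25)) {
    manual <- mean(c(
      stat(beta_matrix(b1), apply_permutation(sch, i, b1$condition), b1$run),
      stat(beta_matrix(b2), apply_permutation(sch, i, b2$condition), b2$run)
    ))
    expect_equal(gt$null_values[i], manual)
  }
  expect_equal(gt$observed,
               mean(c(stat(beta_matrix(b1), b1$condition, b1$run),
                      stat(beta_matrix(b2), b2$condition, b2$run))))
})

test_that("Bonferroni thresholds reproduce the published critical values", {
  expect_equal(signif(bonferroni_threshold(0.05, 18), 2), 2.8e-3)
  expect_equal(signif(bonferroni_threshold(0.05, 6), 2), 8.3e-3)
  expect_equal(bonferroni_threshold(0.04, 1), 0.04)
})

test_that("the ROI gate requires >70% in at least two pairwise decoders", {
  expect_true(roi_gate(c(0.79, 0.75, 0.52)))
  expect_false(roi_gate(c(0.57, 0.56, 0.54)))
  expect_false(roi_gate(c(0.70, 0.70, 0.70)))  # strict inequality
  expect_true(roi_gate(c(0.71, 0.52, 0.75)))
  expect_error(roi_gate(c(1.2, 0.5, 0.5)), "\\[0, 1\\]")
})

test_that("svm and centroid permutation statistics agree on strong signal", {
  means <- condition_means(ip_dist = 20)
  bs <- synthetic_betas(means, n_blocks_per_cond = 4, n_runs = 2,
                        noise_sd = 0.1, seed = 21)
  s_svm <- stat_pairwise_accuracy(c("IP", "CP"), "svm")
  s_cen <- stat_pairwise_accuracy(c("IP", "CP"), "centroid")
  x <- beta_matrix(bs)
  expect_equal(s_svm(x, bs$condition, bs$run), 1)
  expect_equal(s_cen(x, bs$condition, bs$run), 1)
})
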