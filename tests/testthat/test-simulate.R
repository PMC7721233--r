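test_that("condition patterns carry the requested correlations exactly", {
  id3 <- diag(3)
  p <- build_condition_patterns(40, id3, seed = 1)
  g <- crossprod(p)
  expect_equal(unname(diag(g)), rep(1, 3), tolerance = 1e-10)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-10)
  # patterns are mean-free, so they leave the ROI-average response alone
  expect_lt(max(abs(colSums(p))), 1e-10)

  r <- matrix(c(1, 0.2, 0.2, 0.2, 1, 0.9, 0.2, 0.9, 1), 3, 3)
  p2 <- build_condition_patterns(40, r, seed = 2)
  expect_equal(unname(crossprod(p2)), unname(r), tolerance = 1e-6)

  ones <- matrix(1, 3, 3)
  p3 <- build_condition_patterns(40, ones, seed = 3)
  expect_equal(p3[, "CP"], p3[, "NM"], tolerance = 1e-10)

  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(build_condition_patterns(40, bad), "semi-definite")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- synthetic_session_config(
    n_participants = 1, design = make_session_design(n_runs = 2, seed = 5),
    rois = list(roi_pattern_model(n_voxels = 10)), seed = 5)
  s1 <- simulate_participant(cfg, 1)
  s2 <- simulate_participant(cfg, 1)
  expect_identical(s1$V5$runs[[1]]$data, s2$V5$runs[[1]]$data)
  expect_identical(s1$V5$runs[[2]]$nuisance, s2$V5$runs[[2]]$nuisance)
  s3 <- simulate_participant(cfg, 2)
  expect_false(identical(s1$V5$runs[[1]]$data, s3$V5$runs[[1]]$data))
})

test_that("identical condition responses decode at chance", {
  roi <- roi_pattern_model(n_voxels = 20,
                           mean_amplitudes = c(IP = 3, CP = 3, NM = 3),
                           cp_nm_pattern_correlation = 1,
                           ip_pattern_correlation = 1)
  cfg <- synthetic_session_config(
    n_participants = 1, design = make_session_design(n_runs = 4, seed = 6),
    rois = list(roi), noise = noise_model(voxel_noise_sd = 2), seed = 6)
  sim <- simulate_participant(cfg, 1)
  bs <- bind_beta_series(lapply(sim$V5$runs, fit_glm))
  acc <- pairwise_discrimination(bs, c("IP", "CP"))$mean_accuracy
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("the motion-sensitive signature is recovered: a perfectly shared
           CP/NM pattern is undecodable while IP separates", {
  roi <- roi_pattern_model(n_voxels = 40,
                           mean_amplitudes = c(IP = 3.39, CP = 3.05, NM = 3.05),
                           cp_nm_pattern_correlation = 1)
  cfg <- synthetic_session_config(
    n_participants = 1, design = make_session_design(n_runs = 8, seed = 7),
    rois = list(roi), noise = noise_model(voxel_noise_sd = 1), seed = 7)
  sim <- simulate_participant(cfg, 1)
  bs <- bind_beta_series(lapply(sim$V5$runs, fit_glm))
  cpnm <- pairwise_discrimination(bs, c("CP", "NM"))$mean_accuracy
  # 96 tested blocks; binomial 95% band around 0.5 is roughly +/- 0.1
  expect_gt(cpnm, 0.35)
  expect_lt(cpnm, 0.65)
  expect_gt(pairwise_discrimination(bs, c("IP", "CP"))$mean_accuracy, 0.8)
  expect_gt(pairwise_discrimination(bs, c("IP", "NM"))$mean_accuracy, 0.8)
})

test_that("a nearly shared CP/NM pattern stays decodable yet biased", {
  roi <- roi_pattern_model(n_voxels = 40, cp_nm_pattern_correlation = 0.9)
  cfg <- synthetic_session_config(
    n_participants = 1, design = make_session_design(n_runs = 8, seed = 8),
    rois = list(roi), noise = noise_model(voxel_noise_sd = 1), seed = 8)
  sim <- simulate_participant(cfg, 1)
  bs <- bind_beta_series(lapply(sim$V5$runs, fit_glm))
  expect_gt(pairwise_discrimination(bs, c("CP", "NM"))$mean_accuracy, 0.6)
  bias <- cross_decode(bs, c("IP", "NM"), "CP")$fraction_labeled[["NM"]]
  expect_gt(bias, 0.6)
})

test_that("simulated runs round-trip through NIfTI, TSV and motion files", {
  cfg <- noiseless_config(seed = 9, n_voxels = 11, n_runs = 2)
  sim <- simulate_participant(cfg, 1)
  run <- sim$V5$runs[[1]]
  dir <- withr::local_tempdir()
  paths <- write_bold_run(run, dir, "sub01_roi-V5_run01")
  back <- read_bold_run(paths["bold"], paths["mask"], paths["events"],
                        paths["motion"])
  expect_equal(back$data, run$data, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$tr_s, run$tr_s, tolerance = 1e-6)
  expect_equal(back$events$onset_s, run$events$onset_s)
  expect_equal(back$events$condition, run$events$condition)
  expect_equal(unname(back$nuisance), unname(run$nuisance),
               tolerance = 1e-12)
  # GLM betas from the reloaded run match the originals
  expect_equal(beta_matrix(fit_glm(back)), beta_matrix(fit_glm(run)),
               tolerance = 1e-8)
})

test_that("missing input files fail before any computation", {
  expect_error(read_bold_run("nope.nii.gz", "nope.nii.gz", "nope.tsv"),
               "not found")
})
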