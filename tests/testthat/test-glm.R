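test_that("the double-gamma kernel starts at zero, peaks near the configured
           delay, and has one sign change", {
  p <- hrf_params()
  kern <- double_gamma_hrf(p, tr_s = 1.2)
  expect_equal(kern[1], 0)
  expect_equal(max(kern), 1)
  # dense-grid maximisation of the continuous kernel
  tt <- seq(0, 32, by = 0.001)
  h <- opponency:::hrf_continuous(tt, p)
  expect_lt(abs(tt[which.max(h)] - p$peak_delay_s), 0.25)
  signs <- sign(h[tt > 0.01 & h != 0])
  expect_equal(sum(diff(signs) != 0), 1)
})

test_that("an 18-block run yields 18 + 6 + 1 design columns, z-scored", {
  d <- make_session_design(n_runs = 1, seed = 6)
  ev <- tibble::tibble(onset_s = d$onset_s, duration_s = d$duration_s,
                       condition = d$condition, block_id = d$block_id)
  n_vol <- 370
  nuis <- matrix(rnorm(n_vol * 6), n_vol, 6)
  des <- build_beta_series_design(ev, nuis, n_vol, tr_s = 1.2)
  expect_equal(ncol(des$design), 25)
  expect_equal(length(des$block_cols), 18)
  non_int <- des$design[, setdiff(colnames(des$design), "intercept")]
  expect_equal(unname(colMeans(non_int)), rep(0, 24), tolerance = 1e-12)
  expect_equal(unname(apply(non_int, 2, sd)), rep(1, 24), tolerance = 1e-12)
})

test_that("identical blocks at different onsets give time-shifted columns", {
  ev <- tibble::tibble(onset_s = c(12, 60), duration_s = 12,
                       condition = c("IP", "IP"), block_id = c("a", "b"))
  regs <- build_block_regressors(ev, n_volumes = 100, tr_s = 1.2)
  shift <- (60 - 12) / 1.2
  expect_equal(regs[1:(100 - shift), "a"], regs[(shift + 1):100, "b"],
               tolerance = 1e-12)
})

test_that("zero-variance regressors are rejected by name", {
  ev <- tibble::tibble(onset_s = 12, duration_s = 12, condition = "IP",
                       block_id = "a")
  nuis <- cbind(matrix(rnorm(100 * 5), 100, 5), 0)
  expect_error(build_beta_series_design(ev, nuis, 100, 1.2), "motion6")
})

test_that("OLS betas match an independent normal-equations solve", {
  d <- make_session_design(n_runs = 1, seed = 8)
  ev <- tibble::tibble(onset_s = d$onset_s[1:5], duration_s = 12,
                       condition = d$condition[1:5], block_id = d$block_id[1:5],
                       run = 1L)
  withr::with_seed(21, {
    n_vol <- 150
    nuis <- matrix(rnorm(n_vol * 6), n_vol, 6)
    des <- build_beta_series_design(ev, nuis, n_vol, 1.2)
    y <- matrix(rnorm(8 * n_vol), 8, n_vol)
    run <- bold_run(y, 1.2, ev, nuis, run_id = 1)
    bs <- fit_glm(run, des)
    X <- des$design
    oracle <- solve(t(X) %*% X, t(X) %*% t(y))  # normal equations
    expect_equal(beta_matrix(bs),
                 unname(oracle[des$block_cols, , drop = FALSE]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  })
})

test_that("noise-free data constructed from the design are recovered exactly
           and intercept shifts do not touch block betas", {
  cfg <- noiseless_config()
  sim <- simulate_participant(cfg, 1)
  run <- sim$V5$runs[[1]]
  bs <- fit_glm(run, standardize = FALSE)
  truth <- beta_matrix(sim$V5$truth)[sim$V5$truth$run == 1, ]
  expect_equal(beta_matrix(bs), truth, tolerance = 1e-6, ignore_attr = TRUE)

  shifted <- bold_run(run$data + 50, run$tr_s, run$events, run$nuisance,
                      run$run_id)
  bs2 <- fit_glm(shifted, standardize = FALSE)
  expect_equal(beta_matrix(bs2), beta_matrix(bs), tolerance = 1e-8)
})

test_that("pure-noise betas are unbiased around zero", {
  d <- make_session_design(n_runs = 1, seed = 2)
  ev <- dplyr::select(tibble::as_tibble(d), onset_s, duration_s, condition,
                      block_id, run)
  withr::with_seed(5, {
    y <- matrix(rnorm(200 * 370), 200, 370)
    run <- bold_run(y, 1.2, ev, matrix(rnorm(370 * 6), 370, 6), 1)
    bs <- fit_glm(run)
    expect_lt(abs(mean(beta_matrix(bs))), 0.02)
  })
})

test_that("a rank-deficient design names the collinear columns", {
  ev <- tibble::tibble(onset_s = c(12, 12), duration_s = 12,
                       condition = c("IP", "CP"), block_id = c("a", "b"))
  des <- build_beta_series_design(ev, NULL, 100, 1.2)
  y <- matrix(rnorm(300), 3, 100)
  run <- bold_run(y, 1.2, ev, NULL, 1)
  expect_error(fit_glm(run, des), "collinear")
})

test_that("beta recovery error decreases monotonically with noise", {
  rmse <- vapply(c(1, 0.1, 0.01, 0), function(noise_sd) {
    cfg <- synthetic_session_config(
      n_participants = 1,
      design = make_session_design(n_runs = 2, seed = 31),
      rois = list(roi_pattern_model(n_voxels = 15)),
      noise = noise_model(voxel_noise_sd = noise_sd, ar1_coefficient = 0,
                          drift_amplitude = 0, motion_leak_sd = 0),
      participant_jitter_sd = 0, seed = 31)
    sim <- simulate_participant(cfg, 1)
    est <- bind_beta_series(lapply(sim$V5$runs, fit_glm, standardize = FALSE))
    sqrt(mean((beta_matrix(est) - beta_matrix(sim$V5$truth))^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("percent change is zero for constant signal and +100% for doubling", {
  ev <- tibble::tibble(onset_s = 12, duration_s = 12, condition = "IP",
                       block_id = "a")
  const <- bold_run(matrix(100, 2, 40), 1.2, ev, NULL, 1)
  tc <- percent_change_timecourse(const, "IP")
  expect_equal(tc$percent_change, rep(0, 14))

  sig <- matrix(100, 1, 40)
  sig[1, 16] <- 200  # TR index 5 after the onset volume (11)
  run <- bold_run(sig, 1.2, ev, NULL, 1)
  tc2 <- percent_change_timecourse(run, "IP")
  expect_equal(tc2$percent_change[tc2$tr == 5], 100)
  expect_equal(tc2$percent_change[tc2$tr == 4], 0)
})

test_that("the averaging window is TRs 4..13 after onset", {
  tc <- tibble::tibble(tr = 0:13, time_s = (0:13) * 1.2, condition = "IP",
                       percent_change = 0:13)
  expect_equal(average_percent_change(tc), mean(4:13))
  expect_equal(tc$time_s[tc$tr == 4], 4.8)
  flat <- dplyr::mutate(tc, percent_change = 3.39)
  expect_equal(average_percent_change(flat), 3.39)
  short <- tc[tc$tr < 10, ]
  expect_error(average_percent_change(short), "window")
})

test_that("simulated motion-sensitive region shows the IP-dominant
           time course", {
  cfg <- synthetic_session_config(
    n_participants = 1,
    design = make_session_design(n_runs = 2, seed = 41),
    rois = list(roi_pattern_model(n_voxels = 30)),
    noise = noise_model(voxel_noise_sd = 0.5),
    participant_jitter_sd = 0, seed = 41)
  sim <- simulate_participant(cfg, 1)
  avg <- vapply(c("IP", "CP", "NM"), function(cc) {
    average_percent_change(percent_change_timecourse(sim$V5$runs, cc))
  }, numeric(1))
  expect_gt(avg[["IP"]], avg[["CP"]])
  expect_gt(avg[["IP"]], avg[["NM"]])
})
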