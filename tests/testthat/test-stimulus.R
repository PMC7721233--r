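# One block of each condition, rendered once and reused across tests.
render_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_session_design(n_runs = 1, seed = 4)
      cache <<- lapply(c(IP = "IP", CP = "CP", NM = "NM"), function(cc) {
        render_block(d[which(d$condition == cc)[1], ], seed = 20)
      })
    }
    cache
  }
})

test_that("every displayed frame contains the full dot population", {
  for (fr in render_fixture()) {
    expect_equal(unique(unname(table(fr$frame))), 500L)
    per_pair <- table(fr$frame, fr$pair_id)
    expect_true(all(per_pair == 2))
  }
})

test_that("no dot outlives its 150 ms lifetime and all dots stay on screen", {
  geom <- display_geometry()
  for (fr in render_fixture()) {
    expect_true(all(fr$age_frames < 9))
    expect_true(all(abs(fr$x_px) <= geom$resolution_x / 2))
    expect_true(all(abs(fr$y_px) <= geom$resolution_y / 2))
  }
})

test_that("motion energy along the Glass axis cancels exactly", {
  fx <- render_fixture()
  expect_identical(motion_energy_balance(fx$CP), 0)
  expect_identical(motion_energy_balance(fx$NM), 0)
  expect_identical(motion_energy_balance(fx$IP), 0)
})

test_that("counter-phase dots cancel within every single frame", {
  fr <- render_fixture()$CP
  steps <- dplyr::arrange(fr, trial, pair_id, dot, frame) |>
    dplyr::group_by(trial, pair_id, dot) |>
    dplyr::mutate(step = a_units - dplyr::lag(a_units)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(step), !replotted)
  per_frame <- dplyr::summarise(dplyr::group_by(steps, trial, frame),
                                net = sum(step), .groups = "drop")
  expect_true(all(per_frame$net == 0))
})

test_that("counter-phase separation runs 8 px -> crossing -> replot at 8 px", {
  fr <- render_fixture()$CP
  ori <- glass_orientation_stats(fr)
  expect_true(all(ori$separation_px <= 8 + 1e-9))
  at_birth <- fr[fr$age_frames == 0 & fr$dot == 1, ]
  sep0 <- glass_orientation_stats(fr)
  born <- merge(at_birth[, c("frame", "trial", "pair_id")], sep0)
  expect_true(all(abs(born$separation_px - 8) < 1e-9))
})

test_that("in-phase direction split is exactly half and half on every frame", {
  fr <- render_fixture()$IP
  by_frame <- table(fr$frame, fr$direction)
  expect_true(all(by_frame[, "+axis"] == 250))
  expect_true(all(by_frame[, "-axis"] == 250))
  # per pair: 125 pairs each way
  first <- fr[fr$frame == min(fr$frame) & fr$dot == 1, ]
  expect_equal(sum(first$direction == "+axis"), 125)
  expect_equal(sum(first$direction == "-axis"), 125)
})

test_that("nonmotion dots never translate", {
  fr <- render_fixture()$NM
  expect_true(all(fr$direction == "none"))
  moved <- dplyr::arrange(fr, trial, pair_id, dot, frame) |>
    dplyr::group_by(trial, pair_id, dot) |>
    dplyr::mutate(step = a_units - dplyr::lag(a_units),
                  new_life = replotted) |>
    dplyr::filter(!is.na(step), !new_life)
  expect_true(all(moved$step == 0))
})

test_that("pair axes agree with the trial tilt in all conditions", {
  fx <- render_fixture()
  d <- make_session_design(n_runs = 1, seed = 4)
  for (cc in names(fx)) {
    fr <- fx[[cc]]
    ori <- glass_orientation_stats(fr)
    for (t in sort(unique(ori$trial))) {
      expected <- fr$axis_deg[fr$trial == t][1] %% 180
      got <- unique(round(ori$orientation_deg[ori$trial == t], 6)) %% 180
      expect_equal(sort(unique(got)), expected, tolerance = 1e-6)
    }
  }
  # identical orientation support across the three conditions
  supports <- lapply(fx, function(fr) {
    sort(unique(round(glass_orientation_stats(fr)$orientation_deg, 6) %% 180))
  })
  expect_equal(supports$IP, supports$CP)
  expect_equal(supports$IP, supports$NM)
})

test_that("zero-separation pairs are excluded from orientation statistics", {
  fr <- render_fixture()$NM
  wide <- tidyr::pivot_wider(
    dplyr::select(fr, frame, trial, pair_id, dot, x_px, y_px),
    names_from = dot, values_from = c(x_px, y_px))
  n_zero <- sum(wide$x_px_1 == wide$x_px_2 & wide$y_px_1 == wide$y_px_2)
  ori <- glass_orientation_stats(fr)
  expect_equal(nrow(ori), nrow(wide) - n_zero)
  expect_gt(n_zero, 0) # separations 0..8 px are sampled, 0 included
})

test_that("rendering is deterministic given block and seed", {
  d <- make_session_design(n_runs = 1, seed = 4)
  f1 <- render_block(d[1, ], seed = 99)
  f2 <- render_block(d[1, ], seed = 99)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  f3 <- render_block(d[1, ], seed = 100)
  expect_false(identical(f1$x_px, f3$x_px))
})

test_that("dots appear only during trials, not in inter-trial gaps", {
  fr <- render_fixture()$IP
  frames_shown <- unique(fr$frame)
  # trials are 66 frames starting every 96 frames
  in_trial <- unlist(lapply(0:5, function(t) t * 96 + 0:65))
  expect_setequal(frames_shown, in_trial)
  expect_lt(max(frames_shown), attr(fr, "n_frames_block"))
})
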