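#' A single-run BOLD dataset
#'
#' Container for one run of one ROI: a voxels x volumes signal matrix, the
#' repetition time, the block events and the head-motion nuisance table.
#'
#' @param data Voxels x volumes numeric matrix.
#' @param tr_s Repetition time, seconds.
#' @param events Tibble with `onset_s`, `duration_s`, `condition`,
#'   `block_id` (and optionally `run`).
#' @param nuisance Volumes x 6 motion-parameter matrix (or `NULL`).
#' @param run_id Run label (integer or string).
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, events, nuisance = NULL, run_id = 1L) {
  data <- as.matrix(data)
  assert_scalar_number(tr_s, "tr_s", 0, strict = TRUE)
  if (any(events$onset_s + events$duration_s > ncol(data) * tr_s + 1e-9)) {
    abort("events do not fit within the run")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == ncol(data))
  }
  structure(
    list(data = data, tr_s = tr_s, events = events, nuisance = nuisance,
         run_id = run_id),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> run %s: %d voxels x %d volumes, TR %g s, %d blocks\n",
              x$run_id, nrow(x$data), ncol(x$data), x$tr_s, nrow(x$events)))
  invisible(x)
}

#' ROI condition-pattern model
#'
#' The condition geometry of a simulated region of interest. Each condition
#' elicits a mean (univariate) percent-signal amplitude plus a voxel pattern:
#' `response_c = amplitude_c * 1 + pattern_strength * p_c`, where the `p_c`
#' are unit-norm voxel vectors orthogonal to the uniform vector (so ROI-mean
#' percent change equals the amplitude exactly) with pairwise correlations
#' fixed by construction. Setting the CP-NM correlation near 1 makes those
#' two conditions nearly indistinguishable to a pattern classifier while the
#' IP pattern stays distinct -- the opponency signature the decoding stages
#' are designed to detect.
#'
#' The default amplitudes (3.39, 3.08, 3.04 percent for IP, CP, NM) are the
#' group-average V5 percent-change values of the study being emulated; the
#' pattern correlations and strength are simulation choices.
#'
#' @param roi_name Label for the ROI.
#' @param n_voxels Number of voxels.
#' @param mean_amplitudes Named numeric vector of percent-change amplitudes
#'   for IP, CP, NM.
#' @param cp_nm_pattern_correlation Correlation between the CP and NM voxel
#'   patterns.
#' @param ip_pattern_correlation Correlation of the IP pattern with each of
#'   CP and NM.
#' @param pattern_strength Multivariate pattern amplitude in percent-signal
#'   units.
#' @return An object of class `roi_pattern_model`.
#' @export
roi_pattern_model <- function(roi_name = "V5",
                              n_voxels = 60,
                              mean_amplitudes = c(IP = 3.39, CP = 3.08,
                                                  NM = 3.04),
                              cp_nm_pattern_correlation = 0.95,
                              ip_pattern_correlation = 0.2,
                              pattern_strength = 2) {
  stopifnot(all(condition_levels() %in% names(mean_amplitudes)))
  if (abs(cp_nm_pattern_correlation) > 1 || abs(ip_pattern_correlation) > 1) {
    abort("pattern correlations must lie in [-1, 1]")
  }
  structure(
    list(
      roi_name = roi_name,
      n_voxels = as.integer(n_voxels),
      mean_amplitudes = mean_amplitudes[condition_levels()],
      cp_nm_pattern_correlation = cp_nm_pattern_correlation,
      ip_pattern_correlation = ip_pattern_correlation,
      pattern_strength = pattern_strength
    ),
    class = "roi_pattern_model"
  )
}

#' Noise model for simulated BOLD runs
#'
#' @param voxel_noise_sd Marginal standard deviation of the AR(1) Gaussian
#'   voxel noise, in signal units (baseline 100 = percent units).
#' @param ar1_coefficient Lag-1 autocorrelation of the voxel noise, in
#'   `[0, 1)`.
#' @param drift_amplitude Maximum linear drift excursion over a run, signal
#'   units.
#' @param motion_signal_sd Standard deviation of the six simulated
#'   head-motion series (arbitrary units).
#' @param motion_leak_sd Standard deviation of the per-voxel loadings with
#'   which the motion series leak into the voxel signals.
#' @param baseline Baseline signal level.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(voxel_noise_sd = 3,
                        ar1_coefficient = 0.3,
                        drift_amplitude = 1,
                        motion_signal_sd = 1,
                        motion_leak_sd = 0.1,
                        baseline = 100) {
  assert_scalar_number(voxel_noise_sd, "voxel_noise_sd", 0)
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    abort("`ar1_coefficient` must lie in [0, 1)")
  }
  structure(
    list(voxel_noise_sd = voxel_noise_sd, ar1_coefficient = ar1_coefficient,
         drift_amplitude = drift_amplitude,
         motion_signal_sd = motion_signal_sd,
         motion_leak_sd = motion_leak_sd, baseline = baseline),
    class = "noise_model"
  )
}

#' Configuration for a synthetic multi-participant session
#'
#' @param n_participants Number of participants (default 5).
#' @param design A [make_session_design()] design shared by all participants
#'   (each participant's data are simulated independently given the design).
#' @param tr_s Repetition time, seconds (default 1.2).
#' @param rois List of [roi_pattern_model()]s.
#' @param noise A [noise_model()].
#' @param participant_jitter_sd Between-participant variability, expressed as
#'   a fraction of each amplitude and of the pattern norm (default 0.1).
#' @param hrf An [hrf_params()].
#' @param seed Integer seed for the whole session.
#' @return An object of class `synthetic_session_config`.
#' @export
synthetic_session_config <- function(n_participants = 5,
                                     design = make_session_design(seed = 1),
                                     tr_s = 1.2,
                                     rois = list(roi_pattern_model()),
                                     noise = noise_model(),
                                     participant_jitter_sd = 0.1,
                                     hrf = hrf_params(),
                                     seed = 1L) {
  assert_scalar_number(tr_s, "tr_s", 0, strict = TRUE)
  if (nrow(design) == 0) abort("design must contain at least one block")
  if (inherits(rois, "roi_pattern_model")) rois <- list(rois)
  names(rois) <- vapply(rois, `[[`, character(1), "roi_name")
  structure(
    list(n_participants = as.integer(n_participants), design = design,
         tr_s = tr_s, rois = rois, noise = noise,
         participant_jitter_sd = participant_jitter_sd, hrf = hrf,
         seed = as.integer(seed)),
    class = "synthetic_session_config"
  )
}

#' Construct condition pattern vectors with exact pairwise correlations
#'
#' Draws a random orthonormal voxel basis (restricted to the subspace
#' orthogonal to the uniform vector, so patterns do not move the ROI mean)
#' and maps it through the symmetric square root of the requested correlation
#' matrix. The resulting unit-norm vectors have pairwise inner products equal
#' to the requested correlations up to machine precision -- constructed, not
#' sampled.
#'
#' @param n_voxels Number of voxels (must exceed the number of conditions).
#' @param correlations 3x3 symmetric positive semi-definite matrix with unit
#'   diagonal, ordered IP, CP, NM.
#' @param seed Optional integer seed.
#' @return A `n_voxels` x 3 matrix with columns `IP`, `CP`, `NM`.
#' @export
build_condition_patterns <- function(n_voxels, correlations, seed = NULL) {
  k <- ncol(correlations)
  if (!isTRUE(all.equal(correlations, t(correlations))) ||
      !isTRUE(all.equal(diag(correlations), rep(1, k), check.attributes = FALSE))) {
    abort("`correlations` must be symmetric with unit diagonal")
  }
  eig <- eigen(correlations, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    abort("`correlations` is not positive semi-definite")
  }
  root <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), k) %*% t(eig$vectors)
  with_seed_if(seed, {
    raw <- cbind(rep(1, n_voxels), matrix(rnorm(n_voxels * k), n_voxels, k))
    q <- qr.Q(qr(raw))[, -1, drop = FALSE]   # orthonormal, orthogonal to 1
    out <- q %*% root
    colnames(out) <- condition_levels()[seq_len(k)]
    out
  })
}

#' Simulate all runs for one participant
#'
#' For each ROI and run, builds the voxel time series as
#' `baseline + sum_blocks response_block * regressor_block + drift +
#' motion leakage + AR(1) noise`, where each block's regressor is the
#' peak-normalised convolved boxcar from [build_block_regressors()] and the
#' block's voxel response vector follows the ROI's condition-pattern model
#' (with per-participant amplitude and pattern jitter). The noiseless
#' response amplitudes are returned as ground-truth betas for oracle tests.
#'
#' @param config A [synthetic_session_config()].
#' @param participant Participant index (1-based); seeds are derived from
#'   `config$seed` and this index, so participants are independent but
#'   reproducible.
#' @return A list with one element per ROI, each containing `runs` (list of
#'   [bold_run()]) and `truth` (a `beta_series` tibble of ground-truth
#'   response amplitudes).
#' @export
simulate_participant <- function(config, participant) {
  stopifnot(inherits(config, "synthetic_session_config"))
  design <- config$design
  tr <- config$tr_s
  noise <- config$noise
  n_vol <- as.integer(round(run_duration_s(design) / tr))
  runs_idx <- sort(unique(design$run))

  with_seed_if(config$seed * 10007L + participant, {
    out <- lapply(config$rois, function(roi) {
      nv <- roi$n_voxels
      corr <- pattern_correlation_matrix(roi)
      patterns <- build_condition_patterns(nv, corr)
      jit <- config$participant_jitter_sd
      # Between-participant variability: a common response gain plus a
      # rescaling of each condition's deviation from the mean amplitude
      # (both ~10% by default), so condition ordering is preserved while
      # subjects differ in overall responsiveness and effect size.
      gain <- 1 + rnorm(1, 0, jit)
      amp_bar <- mean(roi$mean_amplitudes)
      amps <- gain * (amp_bar + (roi$mean_amplitudes - amp_bar) *
                        (1 + rnorm(3, 0, jit)))
      names(amps) <- condition_levels()
      if (jit > 0) {
        patterns <- apply(patterns, 2, function(p) {
          q <- p + rnorm(nv, 0, jit / sqrt(nv))
          q <- q - mean(q)            # keep patterns mean-free
          q / sqrt(sum(q^2))
        })
      }
      response <- sapply(condition_levels(), function(cc) {
        amps[[cc]] + roi$pattern_strength * patterns[, cc]
      })                               # voxels x 3

      runs <- lapply(runs_idx, function(r) {
        ev <- design[design$run == r, c("onset_s", "duration_s", "condition",
                                        "block_id", "run")]
        regs <- build_block_regressors(ev, n_vol, tr, config$hrf)
        signal <- response[, ev$condition, drop = FALSE] %*% t(regs)
        motion <- simulate_motion(n_vol, noise$motion_signal_sd)
        leak <- matrix(rnorm(nv * 6, 0, noise$motion_leak_sd), nv, 6)
        drift_slope <- runif(nv, -1, 1) * noise$drift_amplitude
        drift <- outer(drift_slope, seq(-1, 1, length.out = n_vol))
        eps <- ar1_noise(nv, n_vol, noise$voxel_noise_sd,
                         noise$ar1_coefficient)
        data <- noise$baseline + signal + drift + leak %*% t(motion) + eps
        bold_run(data, tr, ev, motion, run_id = r)
      })

      truth <- new_beta_series(
        t(response[, design$condition, drop = FALSE]),
        design, run_id = design$run
      )
      list(runs = runs, truth = truth, patterns = patterns,
           amplitudes = amps)
    })
    out
  })
}

#' Simulate a whole group
#'
#' @param config A [synthetic_session_config()].
#' @return A list of [simulate_participant()] results, one per participant.
#' @export
simulate_group <- function(config) {
  lapply(seq_len(config$n_participants), function(i) {
    simulate_participant(config, i)
  })
}

pattern_correlation_matrix <- function(roi) {
  r_ip <- roi$ip_pattern_correlation
  r_cpnm <- roi$cp_nm_pattern_correlation
  matrix(c(1, r_ip, r_ip,
           r_ip, 1, r_cpnm,
           r_ip, r_cpnm, 1), 3, 3,
         dimnames = list(condition_levels(), condition_levels()))
}

# Six smooth motion-like series: scaled random walks.
simulate_motion <- function(n_vol, target_sd) {
  m <- vapply(seq_len(6), function(i) {
    w <- cumsum(rnorm(n_vol))
    w <- w - mean(w)
    s <- sd(w)
    if (s == 0) w else w / s * target_sd
  }, numeric(n_vol))
  colnames(m) <- sprintf("motion%d", seq_len(6))
  m
}

# AR(1) Gaussian noise with marginal sd `sd` and lag-1 coefficient `phi`.
ar1_noise <- function(n_voxels, n_vol, sd, phi) {
  if (sd == 0) return(matrix(0, n_voxels, n_vol))
  innov_sd <- sd * sqrt(1 - phi^2)
  eps <- matrix(rnorm(n_voxels * n_vol, 0, innov_sd), n_voxels, n_vol)
  if (phi > 0) {
    eps[, 1] <- rnorm(n_voxels, 0, sd)
    for (t in 2:n_vol) eps[, t] <- phi * eps[, t - 1] + eps[, t]
  }
  eps
}
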