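# Shared fixtures, all generated in code.

fix_geometry_near <- display_geometry(viewing_distance_cm = 22)
fix_geometry_far <- display_geometry(viewing_distance_cm = 25)

# A small session: 2 runs x 2 blocks per condition.
small_design <- function(seed = 1, n_runs = 2, blocks_per_condition = 2) {
  make_session_design(n_runs = n_runs,
                      blocks_per_condition = blocks_per_condition,
                      seed = seed)
}

# Noise-free single-participant config for oracle recovery tests.
noiseless_config <- function(seed = 7, n_voxels = 20, n_runs = 2, ...) {
  synthetic_session_config(
    n_participants = 1,
    design = make_session_design(n_runs = n_runs, seed = seed),
    rois = list(roi_pattern_model(n_voxels = n_voxels, ...)),
    noise = noise_model(voxel_noise_sd = 0, ar1_coefficient = 0,
                        drift_amplitude = 0, motion_leak_sd = 0),
    participant_jitter_sd = 0,
    seed = seed
  )
}

# Beta series drawn straight from a condition-mean + noise model (no GLM),
# for decoding and permutation tests.
synthetic_betas <- function(means, n_blocks_per_cond = 8, n_runs = 4,
                            noise_sd = 1, seed = NULL) {
  code <- function() {
    conds <- colnames(means)
    per_run <- n_blocks_per_cond / n_runs
    stopifnot(per_run == round(per_run))
    labels <- rep(rep(conds, each = per_run), n_runs)
    runs <- rep(seq_len(n_runs), each = per_run * length(conds))
    x <- t(means[, labels]) +
      matrix(rnorm(length(labels) * nrow(means), 0, noise_sd),
             length(labels), nrow(means))
    as_beta_series(x, labels, runs)
  }
  if (is.null(seed)) code() else withr::with_seed(seed, code())
}

# Condition mean matrix (voxels x conditions) with controllable geometry.
condition_means <- function(n_voxels = 12, ip_dist = 4, cp_nm_dist = 0,
                            seed = 1) {
  withr::with_seed(seed, {
    base <- rnorm(n_voxels)
    u <- rnorm(n_voxels); u <- u / sqrt(sum(u^2))
    v <- rnorm(n_voxels); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    cbind(IP = base + ip_dist * u,
          CP = base,
          NM = base + cp_nm_dist * v)
  })
}
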