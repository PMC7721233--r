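#' Double-gamma haemodynamic response parameters
#'
#' The canonical two-gamma HRF: a positive response lobe peaking about 6 s
#' after stimulus onset minus a delayed undershoot, here parameterised by the
#' lobe modes so that `peak_delay_s` is (approximately) the time-to-peak of
#' the kernel.
#'
#' @param peak_delay_s Mode of the positive lobe, seconds.
#' @param undershoot_delay_s Mode of the undershoot lobe, seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions (scale
#'   parameters), seconds.
#' @param peak_undershoot_ratio Ratio of positive lobe to undershoot
#'   amplitude.
#' @param kernel_length_s Kernel support, seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6,
                       undershoot_delay_s = 16,
                       peak_dispersion = 1,
                       undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6,
                       kernel_length_s = 32) {
  assert_scalar_number(peak_delay_s, "peak_delay_s", 0, strict = TRUE)
  assert_scalar_number(undershoot_delay_s, "undershoot_delay_s", 0, strict = TRUE)
  assert_scalar_number(peak_dispersion, "peak_dispersion", 0, strict = TRUE)
  assert_scalar_number(undershoot_dispersion, "undershoot_dispersion", 0, strict = TRUE)
  assert_scalar_number(peak_undershoot_ratio, "peak_undershoot_ratio", 0, strict = TRUE)
  assert_scalar_number(kernel_length_s, "kernel_length_s", 0, strict = TRUE)
  structure(
    list(
      peak_delay_s = peak_delay_s,
      undershoot_delay_s = undershoot_delay_s,
      peak_dispersion = peak_dispersion,
      undershoot_dispersion = undershoot_dispersion,
      peak_undershoot_ratio = peak_undershoot_ratio,
      kernel_length_s = kernel_length_s
    ),
    class = "hrf_params"
  )
}

#' Sample the double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (positive lobe minus scaled undershoot),
#' each parameterised by its mode (`shape = 1 + delay / dispersion`,
#' `scale = dispersion`), sampled at the repetition time and normalised to a
#' peak of 1.
#'
#' @param params An [hrf_params()].
#' @param tr_s Sampling interval (repetition time), seconds.
#' @return Numeric kernel sampled at `0, tr_s, 2 tr_s, ...` up to
#'   `kernel_length_s`.
#' @export
double_gamma_hrf <- function(params = hrf_params(), tr_s) {
  stopifnot(inherits(params, "hrf_params"))
  assert_scalar_number(tr_s, "tr_s", 0, strict = TRUE)
  t <- seq(0, params$kernel_length_s, by = tr_s)
  h <- hrf_continuous(t, params)
  h / max(h)
}

# Unnormalised double-gamma evaluated at arbitrary times.
hrf_continuous <- function(t, params) {
  dgamma(t, shape = 1 + params$peak_delay_s / params$peak_dispersion,
         scale = params$peak_dispersion) -
    dgamma(t, shape = 1 + params$undershoot_delay_s / params$undershoot_dispersion,
           scale = params$undershoot_dispersion) / params$peak_undershoot_ratio
}

#' Block regressors: boxcars convolved with the HRF
#'
#' One column per event: a boxcar over the block's onset/duration sampled at
#' the acquisition times `(v - 1) * tr_s`, convolved with the double-gamma
#' kernel, and normalised so each column peaks at 1 (so a response of
#' amplitude `a` in the data corresponds to a regression weight of `a`). Both
#' the simulator and the GLM build their regressors through this function,
#' which makes noise-free simulations exactly recoverable.
#'
#' @param events Tibble with `onset_s`, `duration_s` (and optionally
#'   `block_id`) columns.
#' @param n_volumes Number of volumes in the run.
#' @param tr_s Repetition time, seconds.
#' @param hrf An [hrf_params()].
#' @return A `n_volumes` x `nrow(events)` matrix with block ids as column
#'   names.
#' @export
build_block_regressors <- function(events, n_volumes, tr_s,
                                   hrf = hrf_params()) {
  t_vol <- (seq_len(n_volumes) - 1) * tr_s
  if (any(events$onset_s + events$duration_s > max(t_vol) + tr_s)) {
    abort("events extend past the end of the run")
  }
  kern <- double_gamma_hrf(hrf, tr_s)
  cols <- vapply(seq_len(nrow(events)), function(i) {
    box <- as.numeric(t_vol >= events$onset_s[i] &
                        t_vol < events$onset_s[i] + events$duration_s[i])
    conv <- convolve(box, rev(kern), type = "open")
    reg <- conv[seq_len(n_volumes)]
    reg / max(reg)
  }, numeric(n_volumes))
  colnames(cols) <- if ("block_id" %in% names(events)) events$block_id else
    sprintf("block%03d", seq_len(nrow(events)))
  cols
}

#' Build a beta-series design matrix
#'
#' One regressor per stimulus block (boxcar convolved with the double-gamma
#' HRF), the six head-motion nuisance series, and an intercept. Block and
#' nuisance columns are z-scored across volumes by default. Optional
#' discrete-cosine drift columns implement highpass filtering inside the
#' model.
#'
#' @param events Tibble of blocks (`onset_s`, `duration_s`, `condition`,
#'   `block_id`).
#' @param nuisance `n_volumes` x 6 matrix (or data frame) of head-motion
#'   parameters, or `NULL` for none.
#' @param n_volumes Number of volumes.
#' @param tr_s Repetition time, seconds.
#' @param hrf An [hrf_params()].
#' @param standardize Z-score block and nuisance columns (default `TRUE`).
#' @param highpass_s Optional highpass cutoff in seconds; adds discrete
#'   cosine basis columns with periods longer than the cutoff.
#' @return A list with `design` (the matrix), `block_cols` (names of the
#'   block columns, in block order) and `events`.
#' @export
build_beta_series_design <- function(events, nuisance, n_volumes, tr_s,
                                     hrf = hrf_params(), standardize = TRUE,
                                     highpass_s = NULL) {
  events <- events[order(events$onset_s), ]
  blocks <- build_block_regressors(events, n_volumes, tr_s, hrf)
  cols <- list(blocks)
  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    if (nrow(nuis) != n_volumes) {
      abort("nuisance table must have one row per volume")
    }
    colnames(nuis) <- sprintf("motion%d", seq_len(ncol(nuis)))
    cols <- c(cols, list(nuis))
  }
  if (!is.null(highpass_s)) {
    dct <- dct_basis(n_volumes, tr_s, highpass_s)
    if (ncol(dct) > 0) cols <- c(cols, list(dct))
  }
  X <- do.call(cbind, cols)
  if (standardize) {
    X <- apply(X, 2, function(col) {
      s <- sd(col)
      if (s == 0) return(col) # caught below with its name
      (col - mean(col)) / s
    })
    colnames(X) <- unlist(lapply(cols, colnames))
  }
  zero_var <- apply(X, 2, sd) == 0
  if (any(zero_var)) {
    abort(sprintf("zero-variance regressor(s): %s",
                  paste(colnames(X)[zero_var], collapse = ", ")))
  }
  X <- cbind(X, intercept = 1)
  list(design = X, block_cols = colnames(blocks), events = events)
}

# Discrete cosine drift basis (excluding the constant term) with periods
# above `cutoff_s`.
dct_basis <- function(n_volumes, tr_s, cutoff_s) {
  total_s <- n_volumes * tr_s
  k_max <- floor(2 * total_s / cutoff_s)
  if (k_max < 1) return(matrix(numeric(0), n_volumes, 0))
  v <- seq_len(n_volumes) - 0.5
  basis <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * v / n_volumes)
  }, numeric(n_volumes))
  colnames(basis) <- sprintf("dct%d", seq_len(k_max))
  basis
}

#' Fit the beta-series GLM to one run
#'
#' Ordinary least squares per voxel. Block-column coefficients are returned
#' as the beta series in block (onset) order.
#'
#' @param dataset A `bold_run` (see [bold_run()]).
#' @param design The output of [build_beta_series_design()]; built from the
#'   run's own events/nuisance when omitted.
#' @param ... Passed to [build_beta_series_design()] when `design` is `NULL`.
#' @return A `beta_series` tibble: one row per block with `block_id`, `run`,
#'   `condition`, and one `v<i>` column per voxel.
#' @export
fit_glm <- function(dataset, design = NULL, ...) {
  stopifnot(inherits(dataset, "bold_run"))
  n_vol <- ncol(dataset$data)
  if (is.null(design)) {
    design <- build_beta_series_design(dataset$events, dataset$nuisance,
                                       n_vol, dataset$tr_s, ...)
  }
  X <- design$design
  if (nrow(X) != n_vol) {
    abort("design rows must equal the number of volumes")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qx, t(dataset$data))        # p x voxels
  betas <- coefs[design$block_cols, , drop = FALSE]
  new_beta_series(betas, design$events, dataset$run_id)
}

new_beta_series <- function(betas, events, run_id) {
  nv <- ncol(betas)
  bl <- tibble(
    block_id = design_block_ids(events),
    run = if ("run" %in% names(events)) as.integer(events$run) else
      as.integer(run_id),
    condition = events$condition
  )
  mat <- as_tibble(as.data.frame(betas))
  names(mat) <- sprintf("v%03d", seq_len(nv))
  out <- dplyr::bind_cols(bl, mat)
  structure(out, class = c("beta_series", class(out)),
            voxel_cols = names(mat))
}

design_block_ids <- function(events) {
  if ("block_id" %in% names(events)) as.character(events$block_id) else
    sprintf("block%03d", seq_len(nrow(events)))
}

#' Build a beta series from a matrix and labels
#'
#' @param x Blocks x voxels numeric matrix.
#' @param condition Per-block condition labels.
#' @param run Per-block run ids.
#' @param block_id Optional per-block ids.
#' @return A `beta_series` tibble.
#' @export
as_beta_series <- function(x, condition, run, block_id = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(condition), nrow(x) == length(run))
  events <- tibble(
    onset_s = seq_len(nrow(x)), duration_s = 1,
    condition = condition, run = run,
    block_id = block_id %||% sprintf("block%03d", seq_len(nrow(x)))
  )
  new_beta_series(x, events, run_id = run)
}

#' Voxel columns of a beta series
#' @param betas A `beta_series` tibble.
#' @return Character vector of voxel column names.
#' @export
voxel_cols <- function(betas) {
  attr(betas, "voxel_cols") %||% grep("^v[0-9]+$", names(betas), value = TRUE)
}

#' Beta matrix of a beta series
#' @param betas A `beta_series` tibble.
#' @return A blocks x voxels numeric matrix.
#' @export
beta_matrix <- function(betas) {
  as.matrix(betas[, voxel_cols(betas)])
}

#' Combine per-run beta series
#' @param beta_list List of `beta_series` from [fit_glm()], one per run.
#' @return A single `beta_series` tibble.
#' @export
bind_beta_series <- function(beta_list) {
  out <- dplyr::bind_rows(beta_list)
  structure(out, class = c("beta_series", class(tibble())),
            voxel_cols = attr(beta_list[[1]], "voxel_cols"))
}

#' Write / read a beta series as CSV
#' @param betas A `beta_series`.
#' @param path CSV path.
#' @return `path` (write) or the `beta_series` (read).
#' @export
write_beta_series_csv <- function(betas, path) {
  readr::write_csv(betas, path)
  invisible(path)
}

#' @rdname write_beta_series_csv
#' @export
read_beta_series_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  structure(out, class = c("beta_series", class(out)),
            voxel_cols = grep("^v[0-9]+$", names(out), value = TRUE))
}

#' Averaged percent-change time course for one condition
#'
#' For every block of the requested condition, extracts a window of volumes
#' starting at the block onset, normalises each voxel's signal by its value
#' at the onset volume (percent change relative to the first TR of the
#' block), and averages over voxels and blocks.
#'
#' @param runs A `bold_run` or list of `bold_run`s.
#' @param condition Condition label to average.
#' @param window_trs Number of volumes per block window (default 14, enough
#'   to cover the 10-TR averaging window starting at the fourth TR).
#' @return A tibble with `tr` (0-based index from onset), `time_s`,
#'   `condition` and `percent_change`.
#' @export
percent_change_timecourse <- function(runs, condition, window_trs = 14) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  acc <- NULL
  n_blocks <- 0L
  for (run in runs) {
    ev <- run$events[run$events$condition == condition, ]
    if (nrow(ev) == 0) next
    for (i in seq_len(nrow(ev))) {
      i0f <- ev$onset_s[i] / run$tr_s
      if (abs(i0f - round(i0f)) > 1e-6) {
        abort(sprintf("block %s onset is not volume-aligned",
                      design_block_ids(ev)[i]))
      }
      i0 <- as.integer(round(i0f)) + 1L
      if (i0 + window_trs - 1L > ncol(run$data)) {
        abort(sprintf("window exceeds run length for block %s",
                      design_block_ids(ev)[i]))
      }
      base <- run$data[, i0]
      if (any(base == 0)) {
        abort(sprintf("zero onset-TR intensity in block %s",
                      design_block_ids(ev)[i]))
      }
      win <- run$data[, i0:(i0 + window_trs - 1L), drop = FALSE]
      pc <- 100 * (win / base - 1)
      block_mean <- colMeans(pc)
      acc <- if (is.null(acc)) block_mean else acc + block_mean
      n_blocks <- n_blocks + 1L
    }
  }
  if (n_blocks == 0L) {
    abort(sprintf("condition '%s' not present in events", condition))
  }
  tr_s <- runs[[1]]$tr_s
  tibble(
    tr = 0:(window_trs - 1L),
    time_s = (0:(window_trs - 1L)) * tr_s,
    condition = condition,
    percent_change = acc / n_blocks
  )
}

#' Average percent change over the response window
#'
#' Means the percent-change time course over 10 successive TRs (one block
#' length at TR 1.2 s) beginning at the fourth TR after stimulus onset
#' (0-based index 4, i.e. 4.8 s), accounting for the haemodynamic delay.
#'
#' @param timecourse Output of [percent_change_timecourse()].
#' @param start_tr First TR of the averaging window (0-based; default 4).
#' @param n_trs Number of TRs averaged (default 10).
#' @return Scalar mean percent change.
#' @export
average_percent_change <- function(timecourse, start_tr = 4, n_trs = 10) {
  need <- start_tr + n_trs - 1
  if (max(timecourse$tr) < need) {
    abort(sprintf("time course ends at TR %d; window needs TR %d",
                  max(timecourse$tr), need))
  }
  mean(timecourse$percent_change[timecourse$tr %in% start_tr:need])
}
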