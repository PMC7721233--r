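#' Generate a randomized block design for one scanning session
#'
#' Builds the full block schedule for one participant: per run, a seeded
#' random interleaving of equal numbers of in-phase (IP), counter-phase (CP)
#' and nonmotion (NM) blocks. Each block receives a random cardinal Glass
#' orientation (horizontal or vertical) and a randomly ordered set of six
#' trial tilts, exactly three at +15 degrees and three at -15 degrees from
#' the block orientation. Stimulus blocks and blank blocks strictly
#' alternate; each run opens with one blank block so that every stimulus
#' block is preceded by a baseline period.
#'
#' @param n_runs Number of runs (default 8).
#' @param blocks_per_condition Stimulus blocks per condition per run
#'   (default 6, i.e. 18 stimulus blocks per run).
#' @param block_duration_s Stimulus block duration in seconds.
#' @param blank_duration_s Blank (fixation-only) block duration in seconds.
#' @param trial_duration_s Trial duration within a block, seconds.
#' @param iti_s Inter-trial interval (no dots shown), seconds.
#' @param tilt_deg Magnitude of the per-trial tilt from the cardinal
#'   orientation, degrees.
#' @param seed Optional integer seed; identical seeds give identical designs.
#'
#' @return A `session_design`: a tibble with one row per stimulus block and
#'   columns `run`, `block` (within-run index), `block_id` (unique across the
#'   session), `onset_s`, `duration_s`, `condition`, `base_orientation`
#'   (`"horizontal"` or `"vertical"`), and `tilts` (list column of six signed
#'   tilt angles). Trial and blank timings are stored as attributes.
#' @examples
#' design <- make_session_design(n_runs = 8, seed = 1)
#' dplyr::count(design, condition)
#' @export
make_session_design <- function(n_runs = 8,
                                blocks_per_condition = 6,
                                block_duration_s = 12,
                                blank_duration_s = 12,
                                trial_duration_s = 1.1,
                                iti_s = 0.5,
                                tilt_deg = 15,
                                seed = NULL) {
  assert_scalar_number(n_runs, "n_runs", 0)
  assert_scalar_number(blocks_per_condition, "blocks_per_condition", 1)
  empty <- tibble(
    run = integer(), block = integer(), block_id = character(),
    onset_s = double(), duration_s = double(),
    condition = character(), base_orientation = character(),
    tilts = list()
  )
  design <- if (n_runs < 1) {
    empty
  } else {
    with_seed_if(seed, {
      purrr::map_dfr(seq_len(n_runs), function(r) {
        conds <- sample(rep(condition_levels(), blocks_per_condition))
        nb <- length(conds)
        tibble(
          run = as.integer(r),
          block = seq_len(nb),
          block_id = sprintf("run%02d_block%02d", r, seq_len(nb)),
          onset_s = blank_duration_s +
            (seq_len(nb) - 1) * (block_duration_s + blank_duration_s),
          duration_s = block_duration_s,
          condition = conds,
          base_orientation = sample(c("horizontal", "vertical"), nb,
                                    replace = TRUE),
          tilts = purrr::map(seq_len(nb), function(i) {
            sample(rep(c(tilt_deg, -tilt_deg), 3))
          })
        )
      })
    })
  }
  structure(
    design,
    class = c("session_design", class(empty)),
    block_duration_s = block_duration_s,
    blank_duration_s = blank_duration_s,
    trial_duration_s = trial_duration_s,
    iti_s = iti_s,
    tilt_deg = tilt_deg
  )
}

# Duration of one run in seconds (leading blank + alternating blocks).
run_duration_s <- function(design) {
  blank <- attr(design, "blank_duration_s")
  block <- attr(design, "block_duration_s")
  n_blocks <- max(dplyr::count(design, .data$run)$n)
  blank + n_blocks * (block + blank)
}

#' Write a block design as a BIDS-style events table
#'
#' One tab-separated events file per call, with columns `onset`, `duration`,
#' `trial_type` (and `run`, `block_id` as extra columns).
#'
#' @param design A [make_session_design()] result, optionally filtered to one
#'   run.
#' @param path Output path for the TSV file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  events <- tibble(
    onset = design$onset_s,
    duration = design$duration_s,
    trial_type = design$condition,
    run = design$run,
    block_id = design$block_id
  )
  readr::write_tsv(events, path)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path A tab-separated file with at least `onset`, `duration` and
#'   `trial_type` columns.
#' @return A tibble with columns `onset_s`, `duration_s`, `condition`, plus
#'   `run` and `block_id` when present.
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    abort(sprintf("events file %s lacks columns: %s", path,
                  paste(setdiff(need, names(ev)), collapse = ", ")))
  }
  out <- tibble(
    onset_s = as.numeric(ev$onset),
    duration_s = as.numeric(ev$duration),
    condition = as.character(ev$trial_type)
  )
  if ("run" %in% names(ev)) out$run <- as.integer(ev$run)
  if ("block_id" %in% names(ev)) out$block_id <- as.character(ev$block_id)
  if (!"block_id" %in% names(out)) {
    out$block_id <- sprintf("block%03d", seq_len(nrow(out)))
  }
  out
}
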