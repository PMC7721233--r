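#' Render the dot-frame sequence for one stimulus block
#'
#' Generates per-frame dot positions for a 12 s paired-dot Glass-pattern
#' block in one of three conditions:
#'
#' * `CP` (counter-phase): the two dots of a pair start at the maximum
#'   separation along the Glass axis, travel in opposite directions, approach,
#'   cross, and are replotted at a new random location once their separation
#'   returns to the maximum. Each pair starts at a random point of this
#'   trajectory so replotting is temporally staggered.
#' * `IP` (in-phase): both dots of a pair travel in the same direction along
#'   the Glass axis; exactly half of the pairs move one way and half the
#'   other, with a random within-pair separation between zero and the maximum
#'   and random initial ages.
#' * `NM` (nonmotion): dots are static for the duration of a lifetime and are
#'   then replotted, producing onset/offset flicker without translation.
#'
#' All dots obey the limited lifetime (150 ms by default). Dots are shown only
#' during trials: the inter-trial intervals and the tail of the block after
#' the sixth trial contain no dots.
#'
#' Positions are maintained on a subpixel integer grid of
#' `lifetime_frames` units per pixel (1/9 px at the defaults), on which every
#' per-frame displacement is exactly representable; motion-energy sums over
#' the returned frames therefore cancel exactly rather than to rounding
#' error. Pair trajectories are placed so that a dot never leaves the display
#' during its lifetime.
#'
#' @param block One row of a [make_session_design()] design (or any list with
#'   `condition`, `base_orientation` and `tilts` entries).
#' @param config A [glass_config()].
#' @param geometry A [display_geometry()].
#' @param seed Optional integer seed; identical `(block, seed)` give
#'   identical frame sequences.
#'
#' @return A `dot_frames` tibble with one row per dot per frame: `frame`
#'   (0-based, spanning the whole block at the display refresh), `time_s`,
#'   `trial`, `pair_id`, `dot` (1 or 2), `x_px`, `y_px` (display-centred
#'   coordinates, x rightward, y upward), `a_units` (position along the Glass
#'   axis in subpixel units), `axis_deg` (Glass axis angle from horizontal),
#'   `direction` (`"+axis"`, `"-axis"`, or `"none"`), `age_frames`, and
#'   `replotted` (`TRUE` on the first frame of a new lifetime after the
#'   first).
#' @examples
#' design <- make_session_design(n_runs = 1, seed = 1)
#' frames <- render_block(design[1, ], glass_config(), display_geometry(),
#'                        seed = 2)
#' motion_energy_balance(frames)
#' @export
render_block <- function(block, config = glass_config(),
                         geometry = display_geometry(), seed = NULL) {
  cond <- as.character(block$condition)[1]
  if (!cond %in% condition_levels()) {
    abort(sprintf("unknown condition '%s'", cond))
  }
  base_or <- as.character(block$base_orientation)[1]
  tilts <- if (is.list(block$tilts)) block$tilts[[1]] else block$tilts
  base_deg <- switch(base_or, horizontal = 0, vertical = 90,
                     abort("`base_orientation` must be horizontal or vertical"))

  L <- lifetime_frames(config, geometry)      # frames per lifetime
  scale <- L                                  # subpixel units per px
  step_u <- as.integer(config$max_pair_sep_px) # units moved per frame
  if (abs(config$max_pair_sep_px - step_u) > 0) {
    abort("`max_pair_sep_px` must be a whole number of pixels")
  }
  sep_max_u <- step_u * scale                 # max separation, units
  n <- config$n_pairs
  refresh <- geometry$refresh_hz

  trial_s <- attr(block, "trial_duration_s") %||% 1.1
  iti_s <- attr(block, "iti_s") %||% 0.5
  block_s <- block$duration_s[1] %||% 12
  n_tf <- as.integer(round(trial_s * refresh))
  n_if <- as.integer(round(iti_s * refresh))

  with_seed_if(seed, {
    trials <- purrr::map_dfr(seq_along(tilts), function(t) {
      theta <- base_deg + tilts[t]
      tr <- render_trial(cond, n, n_tf, L, step_u, sep_max_u, scale, theta,
                         geometry, config$dot_size_px)
      tr$frame <- tr$frame + (t - 1L) * (n_tf + n_if)
      tr$trial <- as.integer(t)
      tr
    })
    trials$time_s <- trials$frame / refresh
    out <- trials[order(trials$frame, trials$pair_id, trials$dot), ]
    out <- as_tibble(out)
    structure(
      out,
      class = c("dot_frames", class(out)),
      condition = cond,
      units_per_px = scale,
      config = config,
      geometry = geometry,
      n_frames_block = as.integer(round(block_s * refresh))
    )
  })
}

# One trial of `n_tf` frames; returns 0-based local frame indices.
render_trial <- function(cond, n, n_tf, L, step_u, sep_max_u, scale, theta,
                         geometry, dot_size_px) {
  h_max <- sep_max_u / 2

  # Per-pair state: initial age a0, direction s, half-separation hs (units).
  if (cond == "CP") {
    a0 <- sample(0:(L - 1), n, replace = TRUE)
    s <- rep(0L, n)                  # within-pair opposite motion
    hs <- rep(h_max, n)
  } else if (cond == "IP") {
    if (n %% 2 != 0) abort("IP blocks need an even number of pairs")
    half <- n / 2
    ages <- sample(0:(L - 1), half, replace = TRUE)
    # Direction groups are age-yoked: the +axis and -axis halves share the
    # same multiset of initial ages, so the two groups replot in lockstep and
    # the bidirectional stimulus is exactly balanced on every frame.
    a0 <- c(ages, ages)
    s <- c(rep(1L, half), rep(-1L, half))
    ord <- sample.int(n)
    a0 <- a0[ord]; s <- s[ord]
    hs <- sample(0:sep_max_u, n, replace = TRUE) / 2
  } else { # NM
    a0 <- sample(0:(L - 1), n, replace = TRUE)
    s <- rep(0L, n)
    hs <- sample(0:sep_max_u, n, replace = TRUE) / 2
  }

  # Expand to (pair, frame) grid.
  k <- rep(0:(n_tf - 1), each = n)          # frame
  p <- rep(seq_len(n), times = n_tf)        # pair index
  age <- (a0[p] + k) %% L
  life <- (a0[p] + k) %/% L

  # One random centre per (pair, life), constrained to keep both dots on the
  # display for the whole lifetime.
  n_lives <- (a0 + n_tf - 1) %/% L + 1
  life_base <- cumsum(c(0L, n_lives[-n]))
  life_id <- life_base[p] + life + 1L
  life_pair <- rep(seq_len(n), n_lives)

  off <- life_a_extent(cond, life_pair, s, hs, h_max, step_u, L)
  ctr <- sample_pair_centers(length(life_pair), off$lo, off$hi, theta,
                             geometry, scale, dot_size_px)
  c_a <- ctr$a[life_id]
  c_b <- ctr$b[life_id]

  # Along-axis positions of the two dots (exact on the unit grid).
  if (cond == "CP") {
    h <- h_max - step_u * age
    a1 <- c_a + h
    a2 <- c_a - h
    dir1 <- "-axis"; dir2 <- "+axis"
    d1 <- rep(dir1, length(a1)); d2 <- rep(dir2, length(a2))
  } else if (cond == "IP") {
    a_pair <- c_a + s[p] * step_u * age
    a1 <- a_pair + hs[p]
    a2 <- a_pair - hs[p]
    lab <- ifelse(s[p] > 0, "+axis", "-axis")
    d1 <- lab; d2 <- lab
  } else {
    a1 <- c_a + hs[p]
    a2 <- c_a - hs[p]
    d1 <- rep("none", length(a1)); d2 <- d1
  }

  replot <- life > 0L & age == 0L
  ct <- cospi(theta / 180); st <- sinpi(theta / 180)
  xy <- function(a, b) list(x = (a * ct - b * st) / scale,
                            y = (a * st + b * ct) / scale)
  p1 <- xy(a1, c_b); p2 <- xy(a2, c_b)

  m <- length(k)
  data.frame(
    frame = c(k, k),
    trial = 1L,
    pair_id = c(p, p),
    dot = rep(c(1L, 2L), each = m),
    x_px = c(p1$x, p2$x),
    y_px = c(p1$y, p2$y),
    a_units = c(a1, a2),
    axis_deg = theta,
    direction = c(d1, d2),
    age_frames = c(age, age),
    replotted = c(replot, replot),
    time_s = 0
  )
}

# Along-axis extent (units, relative to the pair centre) spanned by either
# dot of a pair over a full lifetime.
life_a_extent <- function(cond, life_pair, s, hs, h_max, step_u, L) {
  if (cond == "CP") {
    list(lo = rep(-h_max, length(life_pair)), hi = rep(h_max, length(life_pair)))
  } else if (cond == "IP") {
    travel <- step_u * (L - 1)
    sp <- s[life_pair]; hp <- hs[life_pair]
    lo <- ifelse(sp > 0, -hp, -travel - hp)
    hi <- ifelse(sp > 0, travel + hp, hp)
    list(lo = lo, hi = hi)
  } else {
    hp <- hs[life_pair]
    list(lo = -hp, hi = hp)
  }
}

# Uniform integer-grid centres (a, b) in Glass-axis coordinates such that the
# points (a + lo, b) and (a + hi, b) both fall on the display with a margin of
# one dot. Rejection sampling against the rotated display rectangle.
sample_pair_centers <- function(m, lo, hi, theta, geometry, scale,
                                dot_size_px) {
  ct <- cospi(theta / 180); st <- sinpi(theta / 180)
  half_w <- geometry$resolution_x / 2 - dot_size_px
  half_h <- geometry$resolution_y / 2 - dot_size_px
  r_max <- ceiling(scale * sqrt(half_w^2 + half_h^2))
  a <- b <- numeric(m)
  todo <- seq_len(m)
  repeat {
    nt <- length(todo)
    if (nt == 0) break
    ca <- sample.int(2 * r_max + 1, nt, replace = TRUE) - r_max - 1
    cb <- sample.int(2 * r_max + 1, nt, replace = TRUE) - r_max - 1
    ok <- rep(TRUE, nt)
    for (off in list(lo[todo], hi[todo])) {
      x <- ((ca + off) * ct - cb * st) / scale
      y <- ((ca + off) * st + cb * ct) / scale
      ok <- ok & abs(x) <= half_w & abs(y) <= half_h
    }
    a[todo[ok]] <- ca[ok]
    b[todo[ok]] <- cb[ok]
    todo <- todo[!ok]
  }
  list(a = a, b = b)
}

#' Net motion energy along the Glass axis of a rendered block
#'
#' Sums the signed frame-to-frame displacement along the Glass axis over all
#' dots and all consecutive frame pairs, excluding replot events (transitions
#' on which a dot was randomly repositioned at the end of its lifetime).
#' Displacements are accumulated on the renderer's exact subpixel grid, so
#' conditions constructed to be motion balanced return exactly zero:
#' counter-phase pairs cancel within a pair, nonmotion dots never move, and
#' in-phase blocks cancel across the enforced half/half direction split.
#'
#' @param frames A `dot_frames` tibble from [render_block()].
#' @return Net signed displacement in pixels (scalar; exactly 0 for a
#'   motion-balanced block).
#' @export
motion_energy_balance <- function(frames) {
  if (length(unique(frames$frame)) < 2) {
    abort("need at least two frames to measure motion energy")
  }
  scale <- attr(frames, "units_per_px") %||% 1
  ord <- order(frames$trial, frames$pair_id, frames$dot, frames$frame)
  tr <- frames$trial[ord]; pid <- frames$pair_id[ord]
  dt <- frames$dot[ord]; fr <- frames$frame[ord]
  a <- frames$a_units[ord]; rep_flag <- frames$replotted[ord]
  i <- seq_len(length(a) - 1)
  same_dot <- tr[i] == tr[i + 1] & pid[i] == pid[i + 1] & dt[i] == dt[i + 1] &
    fr[i + 1] == fr[i] + 1
  moved <- same_dot & !rep_flag[i + 1]
  sum(a[i + 1][moved] - a[i][moved]) / scale
}

#' Within-pair Glass axis orientations of a rendered block
#'
#' Computes, per frame and pair, the orientation of the axis joining the two
#' dots of the pair. By construction every pair in every condition is aligned
#' with the trial's Glass axis, so the three conditions have identical
#' orientation support; pairs at zero separation (possible for in-phase and
#' nonmotion pairs) are excluded because their orientation is undefined.
#'
#' @param frames A `dot_frames` tibble from [render_block()].
#' @return A tibble with columns `frame`, `trial`, `pair_id`,
#'   `orientation_deg` (in `[0, 180)`, from horizontal) and `separation_px`.
#' @export
glass_orientation_stats <- function(frames) {
  if (nrow(frames) == 0) abort("empty frame sequence")
  wide <- tidyr::pivot_wider(
    dplyr::select(frames, "frame", "trial", "pair_id", "dot", "x_px", "y_px"),
    names_from = "dot", values_from = c("x_px", "y_px")
  )
  dx <- wide$x_px_1 - wide$x_px_2
  dy <- wide$y_px_1 - wide$y_px_2
  sep <- sqrt(dx^2 + dy^2)
  ori <- (atan2(dy, dx) * 180 / pi) %% 180
  out <- tibble(
    frame = wide$frame, trial = wide$trial, pair_id = wide$pair_id,
    orientation_deg = ori, separation_px = sep
  )
  out[out$separation_px > 0, ]
}

#' Write rendered dot frames to CSV
#'
#' @param frames A `dot_frames` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  readr::write_csv(
    dplyr::select(frames, "frame", "trial", "pair_id", "dot",
                  "x_px", "y_px", "direction", "age_frames", "replotted"),
    path
  )
  invisible(path)
}
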