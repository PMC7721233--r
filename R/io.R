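#' Write one BOLD run to disk in standard neuroimaging formats
#'
#' Arranges the ROI voxels into a compact 3D box and writes a 4D NIfTI
#' volume, a matching ROI mask NIfTI (nonzero voxels = ROI, numbered in
#' voxel order), a BIDS-style events TSV and a whitespace-delimited
#' six-column motion parameter file -- the same dialects the real-data path
#' reads.
#'
#' @param run A [bold_run()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, e.g. `"sub01_roiV5_run01"`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_bold_run <- function(run, dir, prefix) {
  stopifnot(inherits(run, "bold_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nv <- nrow(run$data); nt <- ncol(run$data)
  dims <- box_dims(nv)
  vol <- array(0, c(dims, nt))
  mask <- array(0, dims)
  flat <- prod(dims)
  idx <- seq_len(nv)
  mask[idx] <- idx
  for (t in seq_len(nt)) {
    slab <- numeric(flat)
    slab[idx] <- run$data[, t]
    vol[, , , t] <- slab
  }
  bold_path <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  events_path <- file.path(dir, paste0(prefix, "_events.tsv"))
  motion_path <- file.path(dir, paste0(prefix, "_motion.txt"))

  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr_s)
  RNifti::writeNifti(img, bold_path, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path, datatype = "double")

  ev <- run$events
  readr::write_tsv(
    tibble(onset = ev$onset_s, duration = ev$duration_s,
           trial_type = ev$condition,
           run = if ("run" %in% names(ev)) ev$run else run$run_id,
           block_id = design_block_ids(ev)),
    events_path
  )
  utils::write.table(run$nuisance, motion_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(bold = bold_path, mask = mask_path, events = events_path,
              motion = motion_path))
}

box_dims <- function(n_voxels) {
  nx <- ceiling(n_voxels^(1 / 3))
  ny <- ceiling(sqrt(n_voxels / nx))
  nz <- ceiling(n_voxels / (nx * ny))
  c(nx, ny, nz)
}

#' Read one BOLD run from NIfTI + sidecar files
#'
#' @param bold_path 4D NIfTI volume.
#' @param mask_path 3D NIfTI ROI mask; nonzero voxels define the ROI. When
#'   the mask stores distinct positive integers they fix the voxel order,
#'   otherwise array order is used.
#' @param events_path Tab-separated events table (`onset`, `duration`,
#'   `trial_type`).
#' @param motion_path Whitespace-delimited motion table, six columns, one
#'   row per volume; `NULL` for none.
#' @param tr_s Repetition time override; defaults to the NIfTI `pixdim`
#'   time step.
#' @param run_id Run label; defaults to the `run` column of the events file
#'   when present.
#' @return A [bold_run()].
#' @export
read_bold_run <- function(bold_path, mask_path, events_path,
                          motion_path = NULL, tr_s = NULL, run_id = NULL) {
  for (p in c(bold_path, mask_path, events_path, motion_path)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  img <- RNifti::readNifti(bold_path)
  vol <- as.array(img)
  if (length(dim(vol)) != 4) abort("BOLD image must be 4D")
  mask <- as.array(RNifti::readNifti(mask_path))
  if (!all(dim(mask) == dim(vol)[1:3])) {
    abort("mask dimensions do not match the BOLD volume")
  }
  sel <- which(mask != 0)
  if (length(sel) == 0) abort("mask selects no voxels")
  vals <- mask[sel]
  if (!any(duplicated(vals)) && all(vals == round(vals)) && all(vals > 0)) {
    sel <- sel[order(vals)]
  }
  nt <- dim(vol)[4]
  flat <- matrix(vol, ncol = nt)
  data <- flat[sel, , drop = FALSE]

  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4 || pd[4] <= 0) {
      abort("TR not recorded in NIfTI header; pass `tr_s`")
    }
    tr_s <- signif(pd[4], 6)  # header stores single precision
  }
  ev <- read_events_tsv(events_path)
  if (is.null(run_id)) {
    run_id <- if ("run" %in% names(ev)) ev$run[1] else 1L
  }
  nuisance <- NULL
  if (!is.null(motion_path)) {
    nuisance <- as.matrix(utils::read.table(motion_path))
    if (nrow(nuisance) != nt) {
      abort("motion table must have one row per volume")
    }
  }
  bold_run(data, tr_s, ev, nuisance, run_id = run_id)
}

#' Write a whole simulated session to disk
#'
#' @param group Output of [simulate_group()].
#' @param dir Output directory.
#' @return Tibble of written file paths (participant, roi, run, file type,
#'   path), invisibly.
#' @export
write_synthetic_session <- function(group, dir) {
  rows <- list()
  for (p in seq_along(group)) {
    for (roi in names(group[[p]])) {
      runs <- group[[p]][[roi]]$runs
      for (r in seq_along(runs)) {
        prefix <- sprintf("sub%02d_roi-%s_run%02d", p, roi, r)
        paths <- write_bold_run(runs[[r]], dir, prefix)
        rows[[length(rows) + 1]] <- tibble(
          participant = p, roi = roi, run = r,
          file = names(paths), path = unname(paths)
        )
      }
    }
  }
  invisible(dplyr::bind_rows(rows))
}
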