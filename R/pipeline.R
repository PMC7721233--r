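#' Pipeline configuration
#'
#' Bundles everything one end-to-end analysis needs. In synthetic mode the
#' data are simulated from a [synthetic_session_config()]; in real mode a
#' file table points at NIfTI volumes, ROI masks, events TSVs and motion
#' files on disk.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param session A [synthetic_session_config()] (synthetic mode).
#' @param files Data frame with columns `participant`, `roi`, `run`,
#'   `bold`, `mask`, `events`, `motion` (real mode).
#' @param n_permutations Permutations for group inference (the full-scale
#'   analysis uses 15,200; the default keeps desk-scale runs tractable).
#' @param alpha Family-wise alpha before Bonferroni correction.
#' @param gate_threshold Group-mean accuracy that must be strictly exceeded
#'   in at least two pairwise classifiers for an ROI to enter the
#'   cross-decoding analysis.
#' @param classifier `"svm"` or `"centroid"`; used for decoding and for the
#'   permutation nulls (observed statistic and null are always computed with
#'   the same classifier).
#' @param cost Linear SVM cost.
#' @param univariate_roi ROI used for the univariate percent-change
#'   analysis; defaults to the first ROI.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for result CSVs and the run
#'   manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            session = synthetic_session_config(),
                            files = NULL,
                            n_permutations = 1000,
                            alpha = 0.05,
                            gate_threshold = 0.70,
                            classifier = c("svm", "centroid"),
                            cost = 1,
                            univariate_roi = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier)
  if (mode == "real") {
    if (is.null(files)) abort("real mode needs a `files` table")
    files <- as_tibble(files)
    need <- c("participant", "roi", "run", "bold", "mask", "events")
    if (!all(need %in% names(files))) {
      abort(sprintf("`files` lacks columns: %s",
                    paste(setdiff(need, names(files)), collapse = ", ")))
    }
    paths <- c(files$bold, files$mask, files$events,
               if ("motion" %in% names(files)) files$motion)
    missing <- paths[!is.na(paths) & !file.exists(paths)]
    if (length(missing) > 0) {
      abort(sprintf("missing input file(s): %s",
                    paste(utils::head(missing, 3), collapse = ", ")))
    }
  }
  structure(
    list(mode = mode, session = session, files = files,
         n_permutations = as.integer(n_permutations), alpha = alpha,
         gate_threshold = gate_threshold, classifier = classifier,
         cost = cost, univariate_roi = univariate_roi,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full motion-opponency analysis pipeline
#'
#' Executes, in order: data simulation (or loading), beta-series GLM
#' estimation, pairwise leave-one-run-out decoding, the 70% ROI gate,
#' cross-decoding of the untrained condition for gated ROIs, group
#' permutation inference with Bonferroni-corrected thresholds, and the
#' univariate percent-change statistics. All stages derive their randomness
#' from the configuration seed, so identical configurations yield identical
#' results.
#'
#' @param config A [pipeline_config()].
#' @return An `opponency_results` list:
#' \describe{
#'   \item{discrimination}{Per-participant fold accuracies per ROI and pair.}
#'   \item{group_discrimination}{Group means with permutation p-values,
#'     Bonferroni threshold, and significance flags.}
#'   \item{gate}{Per-ROI gate decision.}
#'   \item{transfer}{Per-participant cross-decoding fractions (gated ROIs).}
#'   \item{group_transfer}{Group transfer fractions with two-tailed
#'     permutation p-values.}
#'   \item{univariate}{Subject-by-condition table, repeated-measures ANOVA,
#'     pairwise contrasts, and within-subject standard errors.}
#'   \item{manifest}{Seed, configuration summary, stage timings, versions.}
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  pairs <- list(c("IP", "CP"), c("IP", "NM"), c("CP", "NM"))

  betas <- clock("data_and_glm", pipeline_betas(config))
  rois <- names(betas[[1]])
  n_participants <- length(betas)

  # --- pairwise discrimination -------------------------------------------
  disc <- clock("discrimination", {
    purrr::map_dfr(seq_len(n_participants), function(s) {
      purrr::map_dfr(rois, function(roi) {
        purrr::map_dfr(pairs, function(pr) {
          res <- pairwise_discrimination(betas[[s]][[roi]], pr,
                                         cost = config$cost)
          dplyr::mutate(tidy(res), roi = roi, participant = s, .before = 1)
        })
      })
    })
  })
  group_disc <- disc |>
    dplyr::group_by(.data$roi, .data$pair, .data$participant) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop_last") |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop")

  # --- permutation inference for discrimination --------------------------
  labels0 <- betas[[1]][[rois[1]]]$condition
  runs0 <- betas[[1]][[rois[1]]]$run
  scheme <- generate_permutations(labels0, runs0, config$n_permutations,
                                  seed = config$seed + 2000L)
  disc_threshold <- bonferroni_threshold(config$alpha, 3 * length(rois))
  group_disc <- clock("discrimination_inference", {
    purrr::map_dfr(seq_len(nrow(group_disc)), function(i) {
      roi <- group_disc$roi[i]
      pr <- strsplit(group_disc$pair[i], "v")[[1]]
      test <- group_permutation_test(
        purrr::map(betas, roi),
        stat_pairwise_accuracy(pr, method = config$classifier,
                               cost = config$cost),
        scheme, tail = "one"
      )
      dplyr::mutate(group_disc[i, ], p = test$p,
                    threshold = disc_threshold,
                    significant = test$p < disc_threshold)
    })
  })

  # --- ROI gate -----------------------------------------------------------
  gate <- group_disc |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(pass = roi_gate(.data$mean_accuracy,
                                     threshold = config$gate_threshold),
                     .groups = "drop")
  gated <- gate$roi[gate$pass]

  # --- cross-decoding on gated ROIs --------------------------------------
  transfer <- group_transfer <- tibble()
  if (length(gated) > 0) {
    transfer <- clock("cross_decoding", {
      purrr::map_dfr(seq_len(n_participants), function(s) {
        purrr::map_dfr(gated, function(roi) {
          purrr::map_dfr(pairs, function(pr) {
            tested <- setdiff(condition_levels(), pr)
            res <- cross_decode(betas[[s]][[roi]], pr, tested,
                                cost = config$cost)
            dplyr::mutate(glance(res), roi = roi, participant = s,
                          .before = 1)
          })
        })
      })
    })
    bias_threshold <- bonferroni_threshold(config$alpha, 3 * length(gated))
    group_transfer <- clock("transfer_inference", {
      purrr::map_dfr(gated, function(roi) {
        purrr::map_dfr(pairs, function(pr) {
          lev <- condition_order(pr)
          tested <- setdiff(condition_levels(), pr)
          test <- group_permutation_test(
            purrr::map(betas, roi),
            stat_transfer_fraction(pr, tested, toward = lev[1],
                                   method = config$classifier,
                                   cost = config$cost),
            scheme, tail = "two"
          )
          tibble(
            roi = roi, trained = paste(lev, collapse = "v"),
            tested = tested,
            fraction_first = test$observed,
            fraction_second = 1 - test$observed,
            toward = if (test$observed >= 0.5) lev[1] else lev[2],
            p = test$p, threshold = bias_threshold,
            significant = test$p < bias_threshold
          )
        })
      })
    })
  }

  # --- univariate statistics ---------------------------------------------
  univariate <- clock("univariate", {
    uni_roi <- config$univariate_roi %||% rois[1]
    runs_by_subject <- attr(betas, "runs_by_subject")
    subject_tab <- purrr::map_dfr(seq_len(n_participants), function(s) {
      purrr::map_dfr(condition_levels(), function(cc) {
        tc <- percent_change_timecourse(runs_by_subject[[s]][[uni_roi]], cc)
        tibble(participant = s, condition = cc,
               value = average_percent_change(tc))
      })
    })
    anova <- rm_anova_oneway(subject_tab)
    contrasts <- purrr::map_dfr(pairs, function(pr) {
      pairwise_contrast(anova, pr)
    })
    list(roi = uni_roi, table = subject_tab, anova = anova,
         contrasts = contrasts, se = cousineau_se(subject_tab))
  })

  manifest <- list(
    seed = config$seed,
    mode = config$mode,
    classifier = config$classifier,
    n_permutations = config$n_permutations,
    alpha = config$alpha,
    gate_threshold = config$gate_threshold,
    n_participants = n_participants,
    rois = rois,
    timings_s = timings,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("opponency")),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  results <- structure(
    list(discrimination = disc, group_discrimination = group_disc,
         gate = gate, transfer = transfer, group_transfer = group_transfer,
         univariate = univariate, manifest = manifest),
    class = "opponency_results"
  )
  if (!is.null(config$out_dir)) write_results(results, config$out_dir)
  results
}

# Simulate (or read) all runs and fit the beta-series GLMs.
# Returns a list participant -> roi -> beta_series, with the raw runs kept
# in an attribute for the univariate stage.
pipeline_betas <- function(config) {
  if (config$mode == "synthetic") {
    group <- simulate_group(config$session)
    runs_by_subject <- purrr::map(group, function(p) {
      purrr::map(p, "runs")
    })
  } else {
    files <- config$files
    runs_by_subject <- purrr::map(sort(unique(files$participant)), function(s) {
      fs <- files[files$participant == s, ]
      out <- purrr::map(sort(unique(fs$roi)), function(roi) {
        fr <- fs[fs$roi == roi, ]
        purrr::map(seq_len(nrow(fr)), function(i) {
          read_bold_run(fr$bold[i], fr$mask[i], fr$events[i],
                        if ("motion" %in% names(fr)) fr$motion[i] else NULL,
                        run_id = fr$run[i])
        })
      })
      names(out) <- sort(unique(fs$roi))
      out
    })
  }
  betas <- purrr::map(runs_by_subject, function(p) {
    purrr::map(p, function(runs) {
      bind_beta_series(purrr::map(runs, fit_glm))
    })
  })
  attr(betas, "runs_by_subject") <- runs_by_subject
  betas
}

#' @export
print.opponency_results <- function(x, ...) {
  cat("<opponency_results>\n")
  cat(sprintf("  %d participants, ROIs: %s\n", x$manifest$n_participants,
              paste(x$manifest$rois, collapse = ", ")))
  cat("  group discrimination:\n")
  gd <- x$group_discrimination
  for (i in seq_len(nrow(gd))) {
    cat(sprintf("    %-4s %s: %.0f%%  p = %.3g%s\n", gd$roi[i], gd$pair[i],
                100 * gd$mean_accuracy[i], gd$p[i],
                if (gd$significant[i]) " *" else ""))
  }
  if (nrow(x$group_transfer) > 0) {
    cat("  misclassification bias (gated ROIs):\n")
    gt <- x$group_transfer
    for (i in seq_len(nrow(gt))) {
      frac <- max(gt$fraction_first[i], gt$fraction_second[i])
      cat(sprintf("    %-4s trained %s, tested %s: %.0f%% -> %s  p = %.3g%s\n",
                  gt$roi[i], gt$trained[i], gt$tested[i], 100 * frac,
                  gt$toward[i], gt$p[i],
                  if (gt$significant[i]) " *" else ""))
    }
  }
  an <- x$univariate$anova
  cat(sprintf("  univariate (%s): F(%d, %d) = %.2f, p = %.3g\n",
              x$univariate$roi, an$df1, an$df2, an$statistic, an$p.value))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' @param results An `opponency_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(results$discrimination,
                   file.path(dir, "discrimination.csv"))
  readr::write_csv(results$group_discrimination,
                   file.path(dir, "group_discrimination.csv"))
  readr::write_csv(results$gate, file.path(dir, "roi_gate.csv"))
  if (nrow(results$transfer) > 0) {
    readr::write_csv(results$transfer, file.path(dir, "transfer.csv"))
    readr::write_csv(results$group_transfer,
                     file.path(dir, "group_transfer.csv"))
  }
  readr::write_csv(results$univariate$table,
                   file.path(dir, "univariate_table.csv"))
  readr::write_csv(glance(results$univariate$anova),
                   file.path(dir, "univariate_anova.csv"))
  readr::write_csv(results$univariate$contrasts,
                   file.path(dir, "univariate_contrasts.csv"))
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
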