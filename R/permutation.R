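#' Generate a within-run label permutation scheme
#'
#' Each permutation independently shuffles the block slots within every run,
#' so the permuted labelling preserves, within each run, the exact count of
#' every condition label. The scheme is defined on slot indices and is
#' shared: applying the same scheme to every participant realises the
#' "same permutations for all participants" construction that allows
#' per-permutation statistics to be averaged into a single group null.
#'
#' @param labels Per-block condition labels (defines the slot structure).
#' @param runs Per-block run ids, same length as `labels`.
#' @param n Number of permutations (the full-scale analysis uses 15,200;
#'   desk-scale inference typically uses 500-1,000).
#' @param seed Optional integer seed.
#' @return A `permutation_scheme`: list with `labels`, `runs`, and `perms`
#'   (an `n` x `length(labels)` integer matrix of permuted slot indices,
#'   each row permuting indices only within their own run).
#' @export
generate_permutations <- function(labels, runs, n, seed = NULL) {
  if (n < 1) abort("`n` must be at least 1")
  stopifnot(length(labels) == length(runs))
  idx_by_run <- split(seq_along(labels), runs)
  with_seed_if(seed, {
    perms <- matrix(0L, n, length(labels))
    for (i in seq_len(n)) {
      row <- integer(length(labels))
      for (idx in idx_by_run) {
        row[idx] <- idx[sample.int(length(idx))]
      }
      perms[i, ] <- row
    }
    structure(list(labels = labels, runs = runs, perms = perms, n = n),
              class = "permutation_scheme")
  })
}

#' Apply one permutation of a scheme to a label vector
#'
#' @param scheme A [generate_permutations()] scheme.
#' @param i Permutation index (row of the scheme).
#' @param labels Labels to permute; defaults to the scheme's own labels.
#'   Must have the same per-run label counts as the scheme's.
#' @return The permuted label vector.
#' @export
apply_permutation <- function(scheme, i, labels = NULL) {
  labels <- labels %||% scheme$labels
  stopifnot(length(labels) == ncol(scheme$perms))
  labels[scheme$perms[i, ]]
}

#' Group permutation test with participant-averaged null
#'
#' Computes the group statistic (the mean over participants of a per-subject
#' statistic of beta patterns and labels) for the observed labelling and for
#' every permuted labelling of a shared within-run permutation scheme. The
#' per-permutation statistics are averaged across participants to create one
#' group null distribution, and the p-value is the add-one percentile rank
#' of the observed group statistic.
#'
#' @param beta_list List of `beta_series`, one per participant, all with the
#'   same per-run slot structure as the scheme.
#' @param statistic Function `(x, labels, runs) -> scalar`, where `x` is the
#'   blocks x voxels beta matrix. See [stat_pairwise_accuracy()] and
#'   [stat_transfer_fraction()].
#' @param scheme A [generate_permutations()] scheme.
#' @param tail `"one"` (upper tail) or `"two"`.
#' @return A `group_permutation_test`: list with `observed`,
#'   `null_values`, `p`, `tail`, `n_permutations`, and `per_participant`
#'   observed statistics.
#' @export
group_permutation_test <- function(beta_list, statistic, scheme,
                                   tail = c("one", "two")) {
  tail <- match.arg(tail)
  prep <- lapply(beta_list, function(b) {
    list(x = beta_matrix(b), labels = b$condition, runs = b$run)
  })
  obs_each <- vapply(prep, function(p) statistic(p$x, p$labels, p$runs),
                     numeric(1))
  observed <- mean(obs_each)
  null_values <- vapply(seq_len(scheme$n), function(i) {
    mean(vapply(prep, function(p) {
      statistic(p$x, apply_permutation(scheme, i, p$labels), p$runs)
    }, numeric(1)))
  }, numeric(1))
  res <- permutation_p(null_values, observed, tail)
  structure(
    list(observed = observed, per_participant = obs_each,
         null_values = null_values, p = res$p, tail = tail,
         n_permutations = scheme$n),
    class = "group_permutation_test"
  )
}

#' @export
print.group_permutation_test <- function(x, ...) {
  cat(sprintf(
    "<group_permutation_test> observed %.4f, %s-tailed p = %.3g (%d permutations)\n",
    x$observed, x$tail, x$p, x$n_permutations))
  invisible(x)
}

#' Permutation p-value by add-one percentile rank
#'
#' One-tailed: `p = (# null >= observed + 1) / (n + 1)`, so with 15,200
#' permutations the smallest attainable p is `1/15201 = 6.6e-5`. Ties count
#' towards the tail (conservative). Two-tailed: twice the smaller of the
#' upper- and lower-tail p-values, capped at 1.
#'
#' @param null_values Numeric null distribution (one value per permutation).
#' @param observed Observed statistic.
#' @param tail `"one"` or `"two"`.
#' @return A list with `p`, `observed`, `tail`, `n_permutations`.
#' @export
permutation_p <- function(null_values, observed, tail = c("one", "two")) {
  tail <- match.arg(tail)
  n <- length(null_values)
  if (n < 1) abort("empty null distribution")
  upper <- (sum(null_values >= observed) + 1) / (n + 1)
  p <- if (tail == "one") {
    upper
  } else {
    lower <- (sum(null_values <= observed) + 1) / (n + 1)
    min(1, 2 * min(upper, lower))
  }
  list(p = p, observed = observed, tail = tail, n_permutations = n)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_comparisons Number of comparisons.
#' @return The per-comparison critical p (`alpha / n_comparisons`).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  assert_scalar_number(n_comparisons, "n_comparisons", 1)
  alpha / n_comparisons
}

#' ROI gating rule for the cross-decoding analysis
#'
#' Cross-decoding misclassification bias is only interpretable where the
#' pairwise classifiers work: an ROI is admitted when more than 70% group
#' mean accuracy (strict inequality) is reached in at least two of the three
#' pairwise classifiers.
#'
#' @param accuracies Numeric vector of the three pairwise group-mean
#'   accuracies (fractions in `[0, 1]`).
#' @param threshold Accuracy that must be strictly exceeded (default 0.70).
#' @param n_required Minimum number of classifiers above threshold
#'   (default 2).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
roi_gate <- function(accuracies, threshold = 0.70, n_required = 2) {
  if (any(accuracies < 0 | accuracies > 1)) {
    abort("accuracies must lie in [0, 1]")
  }
  sum(accuracies > threshold) >= n_required
}

#' Statistic factory: pairwise decoding accuracy
#'
#' Returns a statistic function for [group_permutation_test()]: the mean
#' leave-one-run-out accuracy of a classifier discriminating the blocks
#' currently labelled as the two conditions of `pair`.
#'
#' @param pair Two condition labels.
#' @param method `"svm"` (the analysis classifier) or `"centroid"` (a fast
#'   nearest-centroid linear rule, useful for large permutation counts and
#'   calibration studies).
#' @param cost SVM cost, when `method = "svm"`.
#' @return Function `(x, labels, runs) -> accuracy`.
#' @export
stat_pairwise_accuracy <- function(pair, method = c("svm", "centroid"),
                                   cost = 1) {
  method <- match.arg(method)
  lev <- sort(pair)
  function(x, labels, runs) {
    keep <- labels %in% lev
    xk <- x[keep, , drop = FALSE]
    lk <- labels[keep]
    rk <- runs[keep]
    run_ids <- sort(unique(rk))
    acc <- numeric(length(run_ids))
    for (i in seq_along(run_ids)) {
      te <- rk == run_ids[i]
      if (method == "svm") {
        clf <- train_linear_classifier(xk[!te, , drop = FALSE], lk[!te],
                                       cost = cost)
        pred <- predict(clf, xk[te, , drop = FALSE])
      } else {
        pred <- centroid_predict(xk[!te, , drop = FALSE], lk[!te],
                                 xk[te, , drop = FALSE], lev)
      }
      acc[i] <- mean(pred == lk[te])
    }
    mean(acc)
  }
}

#' Statistic factory: cross-decoding transfer fraction
#'
#' Statistic for [group_permutation_test()]: the fraction of blocks of the
#' untrained condition labelled as `toward` by a classifier trained on the
#' two conditions of `trained_pair` (leave-one-run-out, accumulated over
#' folds).
#'
#' @param trained_pair Two trained condition labels.
#' @param tested The untrained condition.
#' @param toward The trained label whose fraction is reported.
#' @param method,cost As in [stat_pairwise_accuracy()].
#' @return Function `(x, labels, runs) -> fraction`.
#' @export
stat_transfer_fraction <- function(trained_pair, tested, toward,
                                   method = c("svm", "centroid"), cost = 1) {
  method <- match.arg(method)
  lev <- sort(trained_pair)
  stopifnot(toward %in% lev, !tested %in% lev)
  function(x, labels, runs) {
    run_ids <- sort(unique(runs))
    hits <- 0L
    total <- 0L
    for (r in run_ids) {
      tr <- labels %in% lev & runs != r
      te <- labels == tested & runs == r
      if (!any(te)) next
      if (method == "svm") {
        clf <- train_linear_classifier(x[tr, , drop = FALSE], labels[tr],
                                       cost = cost)
        pred <- predict(clf, x[te, , drop = FALSE])
      } else {
        pred <- centroid_predict(x[tr, , drop = FALSE], labels[tr],
                                 x[te, , drop = FALSE], lev)
      }
      hits <- hits + sum(pred == toward)
      total <- total + sum(te)
    }
    hits / total
  }
}

# Nearest-centroid linear rule; ties go to the first (sorted) level.
centroid_predict <- function(x_train, y_train, x_test, lev) {
  m1 <- colMeans(x_train[y_train == lev[1], , drop = FALSE])
  m2 <- colMeans(x_train[y_train == lev[2], , drop = FALSE])
  w <- m1 - m2
  thr <- sum(w * (m1 + m2)) / 2
  d <- as.matrix(x_test) %*% w - thr
  ifelse(d >= 0, lev[1], lev[2])
}
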