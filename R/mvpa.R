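#' Leave-one-run-out cross-validation folds
#'
#' One fold per run, ordered by run id: the classifier is trained on all
#' other runs and tested on the held-out run, so every block serves exactly
#' once as test data.
#'
#' @param runs Vector of per-block run labels (one entry per block).
#' @return A tibble with `fold`, `test_run` and `train_runs` (list column).
#' @export
leave_one_run_out_folds <- function(runs) {
  ids <- sort(unique(runs))
  if (length(ids) < 2) {
    abort("leave-one-run-out cross-validation needs at least two runs")
  }
  tibble(
    fold = seq_along(ids),
    test_run = ids,
    train_runs = purrr::map(seq_along(ids), function(i) ids[-i])
  )
}

#' Train a linear support vector machine
#'
#' Soft-margin linear SVM (C-classification, cost 1, no feature scaling by
#' default), matching the common default configuration of off-the-shelf SVM
#' libraries. The fitted decision rule is reduced to an explicit weight
#' vector and bias oriented so that a positive decision value predicts the
#' lexicographically first class; a decision value of exactly zero is also
#' assigned to that class, making predictions deterministic.
#'
#' @param x Training matrix (samples x features).
#' @param y Class labels (two classes).
#' @param cost Soft-margin cost parameter `C`.
#' @param scale Standardise features before fitting (default `FALSE`).
#' @return An object of class `linear_svm` with elements `w`, `b`, `levels`.
#' @export
train_linear_classifier <- function(x, y, cost = 1, scale = FALSE) {
  x <- as.matrix(x)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) {
    abort(sprintf("training data must contain exactly two classes, got: %s",
                  paste(lev, collapse = ", ")))
  }
  fit <- e1071::svm(x, factor(y, levels = lev), kernel = "linear",
                    cost = cost, scale = scale, type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients decision values towards whichever class it met first in
  # the training data; normalise to "positive = first sorted level".
  pr <- stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE)
  pos_label <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  if (pos_label != lev[1]) {
    w <- -w
    b <- -b
  }
  if (scale) {
    ctr <- fit$x.scale$`scaled:center`
    scl <- fit$x.scale$`scaled:scale`
    w <- w / scl
    b <- b - sum(w * ctr)
  }
  structure(list(w = w, b = b, levels = lev, cost = cost),
            class = "linear_svm")
}

#' Decision values of a linear classifier
#' @param object A `linear_svm`.
#' @param newdata Matrix of samples x features.
#' @param ... Unused.
#' @return Numeric decision values (`positive` = first level).
#' @export
decision_values <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w + object$b)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  d <- decision_values(object, newdata)
  ifelse(d >= 0, object$levels[1], object$levels[2])
}

# Shared input checking: betas must carry both (or all) conditions per run.
check_conditions_per_run <- function(betas, conditions) {
  miss <- dplyr::group_by(betas, .data$run) |>
    dplyr::summarise(missing = list(setdiff(conditions, .data$condition))) |>
    dplyr::filter(lengths(.data$missing) > 0)
  if (nrow(miss) > 0) {
    abort(sprintf("run %s lacks condition(s): %s", miss$run[1],
                  paste(miss$missing[[1]], collapse = ", ")))
  }
}

#' Pairwise condition decoding with leave-one-run-out cross-validation
#'
#' Trains a linear SVM to discriminate two conditions on all runs but one and
#' tests it on the held-out run; every run serves once as the test set and
#' the final performance is the average over folds.
#'
#' @param betas A `beta_series` (blocks x voxels with `condition` and `run`
#'   labels).
#' @param pair Character vector of two condition labels.
#' @param cost,scale Passed to [train_linear_classifier()].
#' @return A `decoding_result`: list with `pair`, `folds` (tibble of fold,
#'   test_run, n_test, accuracy), `mean_accuracy`, and `confusion` (2x2
#'   counts summed over folds, true condition in rows).
#' @export
pairwise_discrimination <- function(betas, pair, cost = 1, scale = FALSE) {
  stopifnot(length(pair) == 2)
  check_conditions_per_run(betas, pair)
  sub <- betas[betas$condition %in% pair, ]
  x <- beta_matrix(sub)
  folds <- leave_one_run_out_folds(sub$run)
  lev <- condition_order(pair)
  confusion <- matrix(0L, 2, 2, dimnames = list(true = lev, predicted = lev))
  acc <- numeric(nrow(folds))
  n_test <- integer(nrow(folds))
  for (i in seq_len(nrow(folds))) {
    test <- sub$run == folds$test_run[i]
    clf <- train_linear_classifier(x[!test, , drop = FALSE],
                                   sub$condition[!test], cost = cost,
                                   scale = scale)
    pred <- predict(clf, x[test, , drop = FALSE])
    truth <- sub$condition[test]
    acc[i] <- mean(pred == truth)
    n_test[i] <- sum(test)
    confusion <- confusion + table(factor(truth, lev), factor(pred, lev))
  }
  structure(
    list(pair = lev,
         folds = tibble(fold = folds$fold, test_run = folds$test_run,
                        n_test = n_test, accuracy = acc),
         mean_accuracy = mean(acc),
         confusion = confusion),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s vs %s: mean accuracy %.3f over %d folds\n",
              x$pair[1], x$pair[2], x$mean_accuracy, nrow(x$folds)))
  invisible(x)
}

#' Cross-decoding: test a pairwise classifier on the untrained condition
#'
#' Trains the classifier to discriminate the two trained conditions on all
#' runs but one, then labels the held-out run's blocks of the *untrained*
#' third condition, accumulating over the eight folds. The fraction of
#' untrained blocks absorbed by each trained class measures the
#' misclassification bias: a condition represented similarly to one of the
#' trained classes is consistently labelled as that class.
#'
#' @param betas A `beta_series`.
#' @param trained_pair Character vector of the two trained conditions.
#' @param tested The untrained condition whose blocks are classified.
#' @param cost,scale Passed to [train_linear_classifier()].
#' @return A `transfer_result`: list with `trained_pair`, `tested`, `folds`
#'   (per-fold counts), and `fraction_labeled` (named fractions summing
#'   to 1).
#' @export
cross_decode <- function(betas, trained_pair, tested, cost = 1,
                         scale = FALSE) {
  stopifnot(length(trained_pair) == 2, length(tested) == 1)
  if (tested %in% trained_pair) {
    abort("`tested` must not be one of the trained conditions")
  }
  check_conditions_per_run(betas, c(trained_pair, tested))
  lev <- condition_order(trained_pair)
  train_set <- betas[betas$condition %in% trained_pair, ]
  test_set <- betas[betas$condition == tested, ]
  x_train <- beta_matrix(train_set)
  x_test <- beta_matrix(test_set)
  folds <- leave_one_run_out_folds(betas$run)
  counts <- matrix(0L, nrow(folds), 2,
                   dimnames = list(NULL, lev))
  for (i in seq_len(nrow(folds))) {
    tr <- train_set$run != folds$test_run[i]
    te <- test_set$run == folds$test_run[i]
    clf <- train_linear_classifier(x_train[tr, , drop = FALSE],
                                   train_set$condition[tr], cost = cost,
                                   scale = scale)
    pred <- predict(clf, x_test[te, , drop = FALSE])
    counts[i, ] <- c(sum(pred == lev[1]), sum(pred == lev[2]))
  }
  total <- colSums(counts)
  structure(
    list(trained_pair = lev, tested = tested,
         folds = tibble(fold = folds$fold, test_run = folds$test_run,
                        n_test = rowSums(counts),
                        fraction_first = counts[, 1] / pmax(rowSums(counts), 1)),
         counts = total,
         fraction_labeled = total / sum(total)),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf(
    "<transfer_result> trained %s vs %s, tested %s: %.1f%% -> %s, %.1f%% -> %s\n",
    x$trained_pair[1], x$trained_pair[2], x$tested,
    100 * x$fraction_labeled[1], x$trained_pair[1],
    100 * x$fraction_labeled[2], x$trained_pair[2]))
  invisible(x)
}
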