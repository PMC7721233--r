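#' @export
tidy.decoding_result <- function(x, ...) {
  dplyr::mutate(x$folds,
                pair = paste(x$pair, collapse = "v"),
                .before = 1)
}

#' @export
glance.decoding_result <- function(x, ...) {
  tibble(
    pair = paste(x$pair, collapse = "v"),
    mean_accuracy = x$mean_accuracy,
    n_folds = nrow(x$folds),
    n_blocks = sum(x$folds$n_test)
  )
}

#' @export
tidy.transfer_result <- function(x, ...) {
  dplyr::mutate(x$folds,
                trained = paste(x$trained_pair, collapse = "v"),
                tested = x$tested,
                .before = 1)
}

#' @export
glance.transfer_result <- function(x, ...) {
  tibble(
    trained = paste(x$trained_pair, collapse = "v"),
    tested = x$tested,
    fraction_first = x$fraction_labeled[[1]],
    fraction_second = x$fraction_labeled[[2]],
    toward = x$trained_pair[which.max(x$fraction_labeled)],
    n_blocks = sum(x$counts)
  )
}

#' @export
tidy.group_permutation_test <- function(x, ...) {
  tibble(null_value = x$null_values)
}

#' @export
glance.group_permutation_test <- function(x, ...) {
  tibble(observed = x$observed, p.value = x$p, tail = x$tail,
         n_permutations = x$n_permutations,
         null_mean = mean(x$null_values))
}
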