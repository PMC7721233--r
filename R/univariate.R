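#' Subject-by-condition table of averaged percent change
#'
#' @param data Long tibble with columns `participant`, `condition`, `value`
#'   (one averaged percent-change value per participant and condition), or a
#'   wide data frame / matrix (participants x conditions) which is reshaped.
#' @return A tibble `participant`, `condition`, `value` with complete cells.
#' @export
subject_condition_table <- function(data) {
  if (is.matrix(data)) {
    data <- as.data.frame(data)
    data$participant <- seq_len(nrow(data))
    data <- tidyr::pivot_longer(data, -"participant",
                                names_to = "condition", values_to = "value")
  }
  data <- as_tibble(data)
  need <- c("participant", "condition", "value")
  if (!all(need %in% names(data))) {
    abort("need columns participant, condition, value")
  }
  counts <- table(data$participant, data$condition)
  if (any(counts != 1)) {
    abort("table must contain exactly one value per participant x condition")
  }
  data[need]
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject ANOVA of condition means: the condition sum of
#' squares is tested against the subject-by-condition residual, with degrees
#' of freedom `(k - 1, (k - 1)(n - 1))` for `n` participants and `k`
#' conditions. Fitted through `stats::aov()` with a subject error stratum.
#' No sphericity correction is applied by default; the Greenhouse-Geisser
#' correction is available behind a flag.
#'
#' @param table A [subject_condition_table()] (or anything it accepts).
#' @param gg_correction Apply the Greenhouse-Geisser epsilon correction to
#'   the degrees of freedom and p-value (default `FALSE`).
#' @return An `rm_anova` object: list with `statistic` (F), `df1`, `df2`,
#'   `p.value`, `ms_resid`, `n_participants`, `n_conditions`, `ss` (named
#'   sums of squares), `epsilon` (when corrected), and `means`.
#' @export
rm_anova_oneway <- function(table, gg_correction = FALSE) {
  tab <- subject_condition_table(table)
  n <- length(unique(tab$participant))
  k <- length(unique(tab$condition))
  if (n < 2 || k < 2) abort("need at least two participants and conditions")
  tab$participant <- factor(tab$participant)
  tab$condition <- factor(tab$condition)

  fit <- stats::aov(value ~ condition + Error(participant), data = tab)
  within <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- within["condition", "Sum Sq"]
  ss_resid <- within["Residuals", "Sum Sq"]
  df1 <- within["condition", "Df"]
  df2 <- within["Residuals", "Df"]
  ms_resid <- ss_resid / df2
  subj_tab <- summary(fit)[["Error: participant"]][[1]]
  ss_subj <- subj_tab["Residuals", "Sum Sq"]

  tiny <- .Machine$double.eps * max(1, ss_cond, ss_resid)
  exact_fit <- ss_resid < tiny
  f_stat <- if (ss_cond < tiny) 0 else if (exact_fit) Inf else
    (ss_cond / df1) / ms_resid
  eps <- NA_real_
  if (gg_correction) {
    eps <- gg_epsilon(tab)
    p <- pf(f_stat, df1 * eps, df2 * eps, lower.tail = FALSE)
  } else {
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  means <- dplyr::summarise(dplyr::group_by(tab, .data$condition),
                            mean = mean(.data$value), .groups = "drop")
  structure(
    list(statistic = f_stat, df1 = df1, df2 = df2, p.value = p,
         ms_resid = ms_resid, n_participants = n, n_conditions = k,
         ss = c(condition = ss_cond, subject = ss_subj,
                residual = ss_resid),
         epsilon = eps, exact_fit = exact_fit, means = means,
         data = tab),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the subject x condition covariance matrix.
gg_epsilon <- function(tab) {
  wide <- tidyr::pivot_wider(tab, names_from = "condition",
                             values_from = "value")
  m <- as.matrix(wide[, -1])
  s <- stats::cov(m)
  k <- ncol(s)
  dd <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
    mean(s)
  sum(diag(dd))^2 / ((k - 1) * sum(dd^2))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = "condition", statistic = x$statistic, df1 = x$df1,
         df2 = x$df2, p.value = x$p.value)
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p.value, ms_resid = x$ms_resid,
         n_participants = x$n_participants, n_conditions = x$n_conditions)
}

#' Pairwise contrast of two condition means
#'
#' Tests the difference of two condition means against the repeated-measures
#' ANOVA residual error term, so the degrees of freedom are those of the
#' within-subject residual (`(k - 1)(n - 1)`; 8 for five participants and
#' three conditions).
#'
#' @param table A [subject_condition_table()] (or an `rm_anova` fit).
#' @param pair Two condition labels.
#' @return Tibble with `contrast`, `estimate`, `statistic` (t), `df`,
#'   `p.value` (two-sided).
#' @export
pairwise_contrast <- function(table, pair) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  fit <- if (inherits(table, "rm_anova")) table else rm_anova_oneway(table)
  tab <- fit$data
  n <- fit$n_participants
  m1 <- mean(tab$value[tab$condition == pair[1]])
  m2 <- mean(tab$value[tab$condition == pair[2]])
  se <- sqrt(2 * fit$ms_resid / n)
  t_stat <- (m1 - m2) / se
  tibble(
    contrast = paste(pair, collapse = " - "),
    estimate = m1 - m2,
    statistic = t_stat,
    df = fit$df2,
    p.value = 2 * pt(abs(t_stat), fit$df2, lower.tail = FALSE)
  )
}

#' Cousineau within-subject standard errors
#'
#' Removes each participant's overall mean (adding back the grand mean) and
#' computes the standard error of each condition across participants on the
#' centred data, so between-participant offsets do not inflate the error
#' bars of a within-subject design. The Morey sample-size bias factor
#' `sqrt(k / (k - 1))` is available behind a flag (off by default).
#'
#' @param table A [subject_condition_table()] (or anything it accepts).
#' @param morey Apply the Morey correction factor (default `FALSE`).
#' @return Tibble with `condition`, `mean`, `se`.
#' @export
cousineau_se <- function(table, morey = FALSE) {
  tab <- subject_condition_table(table)
  if (length(unique(tab$participant)) < 2) {
    abort("need at least two participants")
  }
  grand <- mean(tab$value)
  centred <- dplyr::mutate(
    dplyr::group_by(tab, .data$participant),
    centred = .data$value - mean(.data$value) + grand
  )
  out <- dplyr::summarise(
    dplyr::group_by(centred, .data$condition),
    mean = mean(.data$value),
    se = stats::sd(.data$centred) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  if (morey) {
    k <- length(unique(tab$condition))
    out$se <- out$se * sqrt(k / (k - 1))
  }
  out
}
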