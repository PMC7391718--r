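#' Two-way fixed-model consistency ICC(3,1)
#'
#' Test-retest reliability across subjects from a two-way (subjects x
#' sessions) ANOVA without interaction:
#' \deqn{ICC(3,1) = \frac{MS_R - MS_E}{MS_R + (k - 1) MS_E},}
#' where \eqn{MS_R} is the between-subject mean square, \eqn{MS_E} the
#' residual mean square and \eqn{k} the number of sessions per subject.
#' As a consistency ICC it ignores additive session effects (a constant
#' offset between sessions gives ICC = 1). The 95% CI and the p-value
#' against ICC = 0 come from the F ratio \eqn{MS_R / MS_E} with degrees of
#' freedom \eqn{(n - 1)} and \eqn{(n - 1)(k - 1)}. The point estimate can be
#' negative; `icc_clipped = max(icc, 0)` is also reported and drives the
#' reliability category (poor < 0.40, fair < 0.60, good < 0.75, excellent
#' >= 0.75; see [classify_reliability()]).
#'
#' @param data A data frame with one value per subject x session.
#' @param subject,session,value Columns (tidy-eval) identifying the subject,
#'   the session, and the measured value. Defaults `subject_id`,
#'   `session_id`, `value`.
#' @return An `"icc_fit"` object; see [tidy.icc_fit()] and
#'   [glance.icc_fit()]. Fields: `icc`, `icc_clipped`, `ci_low`, `ci_high`,
#'   `p_value`, `category`, `n_subjects`, `k`, `ms_between`, `ms_error`,
#'   `f_statistic`, `df1`, `df2`.
#' @examples
#' d <- data.frame(subject_id = rep(1:5, 2), session_id = rep(1:2, each = 5),
#'                 value = c(1:5, 1:5 + 0.5))
#' icc_3_1(d)  # additive offset: ICC = 1
#' @export
icc_3_1 <- function(data, subject = subject_id, session = session_id,
                    value = value) {
  df <- dplyr::transmute(
    as.data.frame(data),
    subject = as.character({{ subject }}),
    session = as.character({{ session }}),
    value = as.numeric({{ value }}))
  if (anyNA(df$value) || any(!is.finite(df$value)))
    stop_config("all values must be finite")
  if (anyDuplicated(df[c("subject", "session")]))
    stop_config("one value per subject per session is required")
  wide <- tidyr::pivot_wider(df, names_from = "session",
                             values_from = "value")
  m <- as.matrix(wide[-1])
  if (anyNA(m))
    stop_config("every subject needs a value in every session")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop_config("ICC needs at least 3 subjects, got %d", n)
  if (k < 2) stop_config("ICC needs at least 2 sessions per subject")

  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ms_r <- ss_rows / df1
  ms_e <- max(ss_err, 0) / df2

  if (ss_total == 0) {
    warning("all values identical; ICC defined as 1 with degenerate CI")
    icc <- 1; ci <- c(1, 1); p <- NA_real_; f <- NaN
  } else if (ms_e == 0) {
    icc <- 1; ci <- c(1, 1); p <- 0; f <- Inf
  } else {
    f <- ms_r / ms_e
    icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    fl <- f / stats::qf(0.975, df1, df2)
    fu <- f * stats::qf(0.975, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  clipped <- max(icc, 0)
  structure(list(icc = icc, icc_clipped = clipped,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 category = classify_reliability(clipped),
                 n_subjects = n, k = k,
                 ms_between = ms_r, ms_error = ms_e,
                 f_statistic = f, df1 = df1, df2 = df2),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f [%.3f, %.3f], p = %s (%s; n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high,
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
              x$category, x$n_subjects, x$k))
  invisible(x)
}

RELIABILITY_LEVELS <- c("poor", "fair", "good", "excellent")

#' Categorise an ICC value
#'
#' The conventional reliability bands: poor (ICC < 0.40), fair
#' (0.40-0.59), good (0.60-0.74), excellent (ICC >= 0.75). The printed
#' convention leaves (0.59, 0.60) and (0.74, 0.75) formally unassigned;
#' contiguous half-open intervals `[0.40, 0.60)` and `[0.60, 0.75)` are used.
#'
#' @param icc_clipped Non-negative ICC value(s) in `[0, 1]` (vectorised).
#' @return An ordered factor with levels poor < fair < good < excellent.
#' @examples
#' classify_reliability(c(0.39, 0.40, 0.62, 0.75))
#' @export
classify_reliability <- function(icc_clipped) {
  if (any(!is.finite(icc_clipped) | icc_clipped < 0 | icc_clipped > 1))
    stop_config("icc_clipped must lie in [0, 1]")
  cut(icc_clipped, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf), right = FALSE,
      labels = RELIABILITY_LEVELS, ordered_result = TRUE)
}
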