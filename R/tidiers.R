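# broom-style tidiers and ggplot2 methods

#' Tidy an ICC fit
#'
#' @param x An `"icc_fit"` from [icc_3_1()].
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `estimate_clipped`, `conf.low`,
#'   `conf.high`, `p.value`, `category`, `n_subjects`.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$icc, estimate_clipped = x$icc_clipped,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 p.value = x$p_value, category = as.character(x$category),
                 n_subjects = x$n_subjects)
}

#' Glance at an ICC fit
#'
#' @param x An `"icc_fit"`.
#' @param ... Unused.
#' @return One-row tibble with the ANOVA machinery: mean squares, F
#'   statistic, degrees of freedom, subject count.
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(ms_between = x$ms_between, ms_error = x$ms_error,
                 statistic = x$f_statistic, df1 = x$df1, df2 = x$df2,
                 n_subjects = x$n_subjects, k = x$k)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reliability table
#'
#' ICC (clipped at 0) against epoch number, with 95% confidence intervals,
#' coloured by connectivity method, faceted by metric and epoch length.
#' Horizontal reference lines mark the poor/fair/good/excellent boundaries.
#'
#' @param object A `"reliability_table"` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_table <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$icc))
  d$epoch_length <- factor(d$epoch_length,
                           labels = paste0(sort(unique(d$epoch_length)), " s"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_epochs,
                                  y = .data$icc_clipped,
                                  colour = .data$method)) +
    ggplot2::geom_hline(yintercept = c(0.4, 0.6, 0.75),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$ci_low, 0),
                                        ymax = pmin(.data$ci_high, 1)),
                           width = 2, alpha = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$epoch_length)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of epochs", y = "ICC(3,1)",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectivity matrix
#'
#' @param cm A `"connectivity_matrix"`.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  d <- tibble::as_tibble(as.data.frame.table(cm$weights,
                                             responseName = "weight"))
  names(d)[1:2] <- c("channel_i", "channel_j")
  ggplot2::ggplot(d, ggplot2::aes(.data$channel_i, .data$channel_j,
                                  fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s connectivity (%g-%g Hz, %d epochs)",
                                  cm$method, cm$band[1], cm$band[2],
                                  cm$n_epochs_used),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
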