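#' Plot per-position error rates
#'
#' Bar chart of the total mismatch rate at each offset from the nascent 3'
#' end, optionally faceted into the specific substitution classes.
#'
#' @param object a [positional_error_table()].
#' @param specific facet by substitution class instead of totals?
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.positional_error_table <- function(object, specific = FALSE, ...) {
  if (specific) {
    d <- dplyr::filter(object$specific, !is.na(.data$rate_percent))
    ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$rate_percent)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::facet_wrap(~substitution, scales = "free_y") +
      ggplot2::labs(x = "offset from 3' end", y = "specific rate (%)") +
      ggplot2::theme_bw()
  } else {
    d <- dplyr::filter(object$total, !is.na(.data$total_rate_percent))
    ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$total_rate_percent)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::scale_x_continuous(breaks = d$offset) +
      ggplot2::labs(x = "offset from 3' end", y = "total error rate (%)") +
      ggplot2::theme_bw()
  }
}

#' Plot a position frequency matrix
#'
#' Stacked per-column base frequencies of the context windows around
#' misincorporated positions (a flat-scaled sequence-logo view).
#'
#' @param object a [position_frequency_matrix()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.position_frequency_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$frequency,
                                  fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "offset from misincorporated position",
                  y = "base frequency", fill = NULL) +
    ggplot2::theme_bw()
}

#' Plot a misincorporation threshold sweep
#'
#' Positions and elongation complexes retained as the per-position event
#' threshold increases.
#'
#' @param sweep tibble from [threshold_sweep()].
#' @return a ggplot.
#' @export
plot_threshold_sweep <- function(sweep) {
  d <- tidyr::pivot_longer(sweep, c("n_positions", "n_ecs"),
                           names_to = "series", values_to = "n")
  d <- d[d$n > 0, , drop = FALSE]  # zeros sit below any log scale
  ggplot2::ggplot(d, ggplot2::aes(.data$threshold, .data$n,
                                  colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "events-per-position threshold", y = "count (log scale)",
                  colour = NULL) +
    ggplot2::theme_bw()
}
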