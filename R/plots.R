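#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a distribution of fitness effects
#'
#' Histograms of beneficial and deleterious fitness effects (deleterious
#' shown as magnitudes), faceted by class.
#'
#' @param object A `lac_dfe` from [build_dfe()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lac_dfe
#' @export
autoplot.lac_dfe <- function(object, bins = 40, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::filter(df, .data$effect != "neutral")
  df <- dplyr::mutate(df, magnitude = abs(.data$delta_fitness))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$magnitude)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::labs(x = "|fitness effect|", y = "count",
                  title = "Distribution of fitness effects") +
    ggplot2::theme_minimal()
}

#' Plot a binned exponential fit
#'
#' Binned empirical density with the fitted exponential curve overlaid.
#'
#' @param object A `lac_expfit` from [fit_exponential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lac_expfit
#' @export
autoplot.lac_expfit <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density), fill = "grey70",
                      width = diff(object$bins$mid[1:2]) * 0.95) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = "effect magnitude", y = "density",
                  subtitle = sprintf("lambda = %.3g, R2 = %.3f", object$lam,
                                     object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot an epistasis scan
#'
#' The ratio of the focal mutation's solo effect to its effect on mutated
#' backgrounds, against background fitness rank, coloured by which parameter
#' carries the background mutation (the clusters visible per background
#' parameter are a feature of the model).
#'
#' @param object A `lac_epistasis` from [epistasis_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lac_epistasis
#' @export
autoplot.lac_epistasis <- function(object, ...) {
  trend <- ratio_vs_background_fitness(object)
  ggplot2::ggplot(trend,
                  ggplot2::aes(x = .data$rank, y = .data$ratio,
                               colour = .data$background_param)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "backgrounds, ordered by fitness",
                  y = expression(Delta * f / Delta * f^"*"),
                  colour = "background\nmutation in") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
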