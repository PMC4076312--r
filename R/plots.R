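#' Plot a fitted mixture over the data histogram
#'
#' Density-scaled histogram of the fitted data with the mixture density and
#' its weighted components overlaid.
#'
#' @param object A `mixture_fit`.
#' @param binwidth Histogram bin width in index units (default 5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_fit <- function(object, binwidth = 5, ...) {
  if (is.null(object$model)) abort("fit failed; nothing to plot")
  grid <- seq(min(object$data) - 10, max(object$data) + 10, length.out = 512)
  dens <- tibble(x = grid, density = dmixture(grid, object$model))
  comp <- purrr::pmap_dfr(object$model,
    function(mean, sd, weight) tibble(x = grid, component = sprintf("mu=%.1f", mean),
                                      density = weight * dnorm(grid, mean, sd)))
  ggplot2::ggplot(tibble(x = object$data), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey85",
                            colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density, group = .data$component),
                       linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$density),
                       linewidth = 1) +
    ggplot2::labs(x = "laterality index", y = "density")
}

#' Plot an AICc model-selection profile
#'
#' @param object A `mixture_selection`.
#' @param ... Unused.
#' @return A ggplot of AICc against the number of components, the selected
#'   count highlighted.
#' @export
autoplot.mixture_selection <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n, y = .data$aicc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n == object$best_n),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "black")) +
    ggplot2::labs(x = "number of components", y = "AICc")
}

#' Plot an atypical-occurrence regression
#'
#' @param object An `occurrence_fit`.
#' @param ... Unused.
#' @return A ggplot of occurrence against category mid-value with the OLS
#'   line.
#' @export
autoplot.occurrence_fit <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$mid, y = .data$occurrence)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "manual preference category mid-value",
                  y = "atypical occurrence (%)", size = "n")
}
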