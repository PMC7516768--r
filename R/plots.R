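#' Double-logarithmic size-distribution plot
#'
#' Log-binned empirical density with an optional fitted or predicted
#' cutoff power law overlaid.
#'
#' @param sizes Vector of sizes/degrees (or an `urn_run` / `network_run`).
#' @param fit Optional `plcut_fit` or `maxent_solution` to overlay.
#' @param ratio Geometric bin ratio for the histogram.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(sizes, fit = NULL, ratio = 1.5) {
  if (inherits(sizes, "urn_run")) sizes <- sizes$sizes
  if (inherits(sizes, "network_run")) sizes <- sizes$degree_samples
  h <- log_binned_histogram(sizes, ratio = ratio)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$center, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "size n", y = "P(n)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- exp(seq(log(min(h$center)), log(max(h$center)),
                    length.out = 200))
    pmf <- plcut_pmf(fit$alpha, fit$beta, a0 = fit$a0,
                     n_max = max(ceiling(max(sizes) * 2), 1000))
    dens <- approxfun(pmf$n, pmf$prob)
    line <- tibble(center = grid, density = dens(grid))
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}

#' @method autoplot plcut_fit
#' @export
autoplot.plcut_fit <- function(object, sizes, ...) {
  plot_size_distribution(sizes, fit = object, ...)
}

#' @method autoplot omega_fit
#' @export
autoplot.omega_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$center, y = .data$sd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(center = object$bins$center,
                    sd = exp(object$intercept +
                               object$omega * log(object$bins$center))),
      colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "size n",
                  y = "sd of one-iteration change",
                  subtitle = sprintf("omega = %.3f", object$omega)) +
    ggplot2::theme_minimal()
}

#' Growth-rate distribution plot
#'
#' Log-density of pooled growth rates (the tent shape) with the normalized
#' incomplete-Gamma closed form overlaid.
#'
#' @param g Vector of growth rates (e.g. from
#'   [empirical_growth_rates()]`$g`).
#' @param n0,c Parameters of the closed-form overlay; `NULL` skips it.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_growth_rates <- function(g, n0 = 1, c = NULL, bins = 80) {
  br <- seq(min(g), max(g), length.out = bins + 1)
  h <- graphics::hist(g, breaks = br, plot = FALSE)
  emp <- tibble(g = h$mids, density = h$density) |>
    dplyr::filter(.data$density > 0)
  p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$g, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "growth rate g", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(c)) {
    cf <- closed_form_normalized(n0 = n0, c = c)$density |>
      dplyr::filter(.data$g >= min(br), .data$g <= max(br))
    p <- p + ggplot2::geom_line(data = cf, colour = "firebrick")
  }
  p
}
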