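#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted mixture over the error histogram
#'
#' Histogram of the signed localization errors with the fitted mixture density
#' overlaid (target von Mises + uniform guess floor, and swap components when
#' present, via the fit's point estimates).
#'
#' @param object A `mixture_fit`.
#' @param binwidth Histogram bin width, degrees.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, binwidth = 10, ...) {
  errs <- tibble::tibble(error = object$errors)
  p <- object$point
  grid <- seq(-180, 180, length.out = 721)
  dens <- p$p_u / 360
  if (p$p_t > 0 && !is.na(p$kappa)) {
    dens <- dens + p$p_t * dvonmises_deg(grid, 0, p$kappa)
  }
  curve_df <- tibble::tibble(error = grid, density = dens)
  ggplot2::ggplot(errs, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, boundary = 0,
                            fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(y = .data$density), colour = "#C03028",
                       linewidth = 0.9) +
    ggplot2::labs(
      x = "signed localization error (deg)", y = "density (per deg)",
      title = sprintf("%s fit (%s): p_t = %.2f, kappa = %.1f",
                      object$model, object$method, p$p_t,
                      ifelse(is.na(p$kappa), NA, p$kappa))) +
    ggplot2::theme_minimal()
}

#' Overlay group posterior densities for one parameter
#'
#' @param samples Named list of numeric posterior draws, one element per group.
#' @param parameter Axis label for the parameter.
#' @return A ggplot of the kernel densities, annotated with the pairwise
#'   percent overlap when exactly two groups are given.
#' @export
plot_group_posteriors <- function(samples, parameter = "kappa") {
  stopifnot(is.list(samples), length(samples) >= 1, !is.null(names(samples)))
  df <- dplyr::bind_rows(purrr::imap(samples, function(v, nm) {
    tibble::tibble(group = nm, value = v)
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.45, colour = NA) +
    ggplot2::labs(x = parameter, y = "posterior density") +
    ggplot2::theme_minimal()
  if (length(samples) == 2) {
    ov <- posterior_overlap(samples[[1]], samples[[2]])
    gg <- gg + ggplot2::ggtitle(sprintf("overlap = %.2f%%", ov))
  }
  gg
}
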