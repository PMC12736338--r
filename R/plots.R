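# ggplot2 methods for the package's curve and comparison objects.

#' Plot a broadened spectrum
#'
#' @param object a `spectrum_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectrum_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_ev,
                                       y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Energy (eV)", y = "Intensity (arb. units)") +
    ggplot2::theme_minimal()
}

#' Plot a stick spectrum over its broadened envelope
#'
#' @param sticks a stick tibble.
#' @param fwhm,grid broadening used for the envelope; see
#'   [convolve_gaussian()].
#' @return a ggplot.
#' @export
plot_sticks <- function(sticks, fwhm = 0.3, grid = default_grid) {
  env <- ensemble_spectrum(sticks, fwhm, grid)
  scale <- max(env$intensity) / max(sticks$strength)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = sticks,
      ggplot2::aes(x = .data$energy_ev, xend = .data$energy_ev,
                   y = 0, yend = .data$strength * scale),
      alpha = 0.3, colour = "grey40") +
    ggplot2::geom_line(
      data = env,
      ggplot2::aes(x = .data$energy_ev, y = .data$intensity),
      colour = "firebrick", linewidth = 0.7) +
    ggplot2::labs(x = "Energy (eV)", y = "Intensity (arb. units)") +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object an `rdf_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rdf_curve <- function(object, ...) {
  lab <- attr(object, "pair_label")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = if (!is.null(lab)) paste(lab, collapse = " – ")) +
    ggplot2::theme_minimal()
}

#' Plot a running coordination number
#'
#' @param object an `rcn_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rcn_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$n)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "r (Å)", y = "n(r)") +
    ggplot2::theme_minimal()
}

#' Bar plot of solvatochromic shifts per variant
#'
#' @param object a `variant_comparison` from [compare_variants()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variant_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$variant,
                                       y = .data$delta_e_ev)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = NULL, y = expression(Delta * E ~ "(eV)")) +
    ggplot2::theme_minimal()
}
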