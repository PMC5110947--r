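# Plotting helpers: ggplot2 views of the main result types.

#' Plot normalized MSF profiles with optional baseline thresholds
#'
#' @param spectrum A [gnm_modes()] result.
#' @param mode_sets Named list of high-frequency rank vectors (see
#'   [msf_profile()]).
#' @param rules Optional list of [threshold_rule()] objects drawn as
#'   horizontal lines.
#' @return A ggplot.
#' @export
plot_msf_profile <- function(spectrum, mode_sets = list(hm1 = 1),
                             rules = NULL) {
  df <- msf_profile(spectrum, mode_sets)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$node, .data$msf,
                                        colour = .data$mode_set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue (trace position)", y = "normalized MSF",
                  colour = "modes") +
    ggplot2::theme_minimal()
  if (!is.null(rules)) {
    thetas <- vapply(rules, rule_theta, numeric(1), n = spectrum$n)
    p <- p + ggplot2::geom_hline(yintercept = thetas, linetype = "dashed")
  }
  p
}

#' @method autoplot hotspot_grid
#' @export
autoplot.hotspot_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$cutoff, .data$f1,
                               colour = factor(.data$mode),
                               shape = factor(.data$window))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "GNM cutoff (Å)", y = "cross-validated F1",
                  colour = "mode (i or m)", shape = "window") +
    ggplot2::theme_minimal()
}

#' @method autoplot gnb
#' @export
autoplot.gnb <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(class = factor(.data$class, c(0, 1),
                                 c("non-hot spot", "hot spot"))) |>
    ggplot2::ggplot(ggplot2::aes(.data$term, .data$mean,
                                 ymin = .data$mean - sqrt(.data$variance),
                                 ymax = .data$mean + sqrt(.data$variance),
                                 colour = .data$class)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(0.4),
                             fatten = 1.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "feature mean ± sd", colour = NULL) +
    ggplot2::theme_minimal()
}
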