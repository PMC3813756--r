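#' Plot a simulated trajectory
#'
#' Forest cover (and optionally the other recorded series) against time.
#'
#' @param object A `forest_trajectory`.
#' @param vars Columns to draw; default forest cover only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot forest_trajectory
#' @export
autoplot.forest_trajectory <- function(object, vars = "x", ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("t", vars)],
                              -"t", names_to = "series")
  labels <- c(x = "forested", y = "just deforested", w = "just reforested",
              r = "deforestation rate", V_F = "V_F", V_D = "V_D")
  long$series <- factor(long$series, levels = vars,
                        labels = labels[vars])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "year", y = NULL, colour = NULL,
                  title = sprintf("%s engine", attr(object, "engine")),
                  subtitle = format(attr(object, "params"))) +
    ggplot2::coord_cartesian(ylim = if (all(vars %in% c("x", "y", "w", "r"))) c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot equilibrium forest cover against the recovery rate
#'
#' Draws `x_star` versus `mu`, one curve per governance level, from a
#' [sweep_parameters()] result — the standard equilibrium map of governance
#' strength against recovery rate.
#'
#' @param sweep A tibble from [sweep_parameters()] containing `mu`, `g` and
#'   `x_star`.
#' @return A ggplot object.
#' @export
plot_equilibrium_map <- function(sweep) {
  if (!all(c("mu", "g", "x_star") %in% names(sweep))) {
    abort("`sweep` must contain columns `mu`, `g`, `x_star`.")
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$mu, y = .data$x_star,
                                      colour = factor(.data$g))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "forest recovery rate μ",
                  y = "equilibrium forest cover x*",
                  colour = "g'") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
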