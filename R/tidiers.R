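#' Tidy an interior equilibrium
#'
#' @param x A `forest_equilibrium` from [interior_equilibrium()].
#' @param ... Unused.
#' @return A one-row tibble with `x_star`, `y_star`, `r_star`,
#'   `delta_V_star`, `V_F_star`, `V_D_star`, `exists`.
#' @method tidy forest_equilibrium
#' @export
tidy.forest_equilibrium <- function(x, ...) {
  tibble(
    x_star = x$x_star, y_star = x$y_star, r_star = x$r_star,
    delta_V_star = x$delta_V_star, V_F_star = x$V_F_star,
    V_D_star = x$V_D_star, exists = x$exists
  )
}

#' Tidy a regime report
#'
#' @param x A `regime_report` from [classify_regime()].
#' @param ... Unused.
#' @return A one-row tibble with the regime label and its diagnostics.
#' @method tidy regime_report
#' @export
tidy.regime_report <- function(x, ...) {
  tibble(
    regime = x$regime, mean_cover = x$mean_cover, amplitude = x$amplitude,
    dominant_period = x$dominant_period, spectral_radius = x$spectral_radius,
    converged = x$converged
  )
}

#' One-row summary of a simulated trajectory
#'
#' @param x A `forest_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: engine, years simulated, mean/min/max forest
#'   cover and mean deforestation rate over the post-burn-in half.
#' @method glance forest_trajectory
#' @export
glance.forest_trajectory <- function(x, ...) {
  n <- nrow(x)
  window <- (floor(n / 2) + 1):n
  tibble(
    engine = attr(x, "engine"),
    n_years = n,
    mean_cover = mean(x$x[window]),
    min_cover = min(x$x[window]),
    max_cover = max(x$x[window]),
    mean_rate = mean(x$r[window])
  )
}
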