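#' Parameter sweep over scenarios
#'
#' Evaluates the model over a grid of parameter combinations. Each row of
#' `grid` may supply any of `b`, `c`, `g`, `alpha`, `mu`, `governance` (and,
#' for the agent engine, `seed`); missing columns are filled from
#' `defaults`. For every combination the closed-form or numerical interior
#' equilibrium is computed, and (optionally) a trajectory is simulated and
#' classified. Rows are processed, and returned, in grid order.
#'
#' @param grid A data frame of parameter combinations.
#' @param defaults A [forest_params()] object providing unswept parameters.
#' @param engine `"meanfield"` (deterministic) or `"agent"` (stochastic).
#' @param classify If `TRUE` (default), simulate each scenario and attach
#'   its regime classification; if `FALSE`, only equilibria are computed
#'   (much faster for dense equilibrium maps).
#' @param horizon Years to simulate when classifying.
#' @param n_parcels Parcel count for the agent engine.
#' @param seed Default seed for the agent engine (a `seed` column in `grid`
#'   overrides it).
#' @param init Initial densities for the mean-field engine.
#' @return A tibble with one row per grid row: the parameter columns plus
#'   `x_star`, `equilibrium_exists`, `spectral_radius`, and, when
#'   `classify = TRUE`, `regime`, `mean_cover`, `amplitude`,
#'   `dominant_period`.
#' @examples
#' grid <- tidyr::expand_grid(mu = c(0.1, 0.5), g = c(0, 5))
#' sweep_parameters(grid, defaults = forest_params(governance = "yearly_incentive"),
#'                  classify = FALSE)
#' @export
sweep_parameters <- function(grid,
                             defaults = forest_params(),
                             engine = c("meanfield", "agent"),
                             classify = TRUE,
                             horizon = 2000,
                             n_parcels = 10000,
                             seed = 1L,
                             init = c(x = 0.5, y = 0, w = 0)) {
  engine <- match.arg(engine)
  check_params(defaults)
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    abort("`grid` must be a data frame with at least one row.")
  }
  known <- c("b", "c", "g", "alpha", "mu", "governance", "seed")
  unknown <- setdiff(names(grid), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown grid column(s): %s.", paste(unknown, collapse = ", ")))
  }

  grid <- as_tibble(grid)
  purrr::pmap_dfr(grid, function(...) {
    row <- list(...)
    p <- forest_params(
      b = row$b %||% defaults$b,
      c = row$c %||% defaults$c,
      g = row$g %||% defaults$g,
      alpha = row$alpha %||% defaults$alpha,
      mu = row$mu %||% defaults$mu,
      governance = row$governance %||% defaults$governance
    )
    eq <- interior_equilibrium(p)
    rad <- if (eq$exists && eq$x_star > 0 && eq$x_star < 1) {
      tryCatch(jacobian_spectral_radius(p), error = function(e) NA_real_)
    } else {
      NA_real_
    }
    res <- tibble(
      b = p$b, c = p$c, g = p$g, alpha = p$alpha, mu = p$mu,
      governance = p$governance,
      x_star = eq$x_star, equilibrium_exists = eq$exists,
      spectral_radius = rad
    )
    if (classify) {
      traj <- if (engine == "meanfield") {
        simulate_meanfield(p, horizon = horizon, init = init)
      } else {
        simulate_agents(p, n_parcels = n_parcels, horizon = horizon,
                        seed = row$seed %||% seed)
      }
      rep <- classify_regime(traj, params = p)
      res <- dplyr::mutate(res,
        regime = rep$regime, mean_cover = rep$mean_cover,
        amplitude = rep$amplitude, dominant_period = rep$dominant_period)
    }
    res
  })
}
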