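# The full mean-field map as a vector function of the state
# (x, y, [w,] V_F, V_D), used for linearization. Mirrors step_densities()
# without the empty-class guards, which never bind at an interior equilibrium.
meanfield_map <- function(state, params) {
  refo <- params$governance == "reforestation_incentive"
  x <- state[1L]; y <- state[2L]
  w <- if (refo) state[3L] else 0
  V_F <- state[length(state) - 1L]
  V_D <- state[length(state)]

  pi_F <- params$b
  pi_D <- params$c * y / (1 - x)
  pi_gF <- switch(params$governance,
    none = 0,
    yearly_incentive = params$g,
    deforestation_penalty = params$g * y / (1 - x),
    reforestation_incentive = params$g * w / x
  )
  a <- params$alpha
  V_Fn <- (1 - a) * V_F +
    a * (pi_F + if (params$governance %in%
                    c("yearly_incentive", "reforestation_incentive")) pi_gF else 0)
  V_Dn <- (1 - a) * V_D +
    a * (pi_D - if (params$governance == "deforestation_penalty") pi_gF else 0)
  r <- plogis(V_Dn - V_Fn)
  xn <- (1 - r) * x + params$mu * (1 - x)
  yn <- r * x
  if (refo) {
    c(xn, yn, params$mu * (1 - x), V_Fn, V_Dn)
  } else {
    c(xn, yn, V_Fn, V_Dn)
  }
}

equilibrium_state_vector <- function(eq) {
  p <- eq$params
  if (p$governance == "reforestation_incentive") {
    c(eq$x_star, eq$y_star, p$mu * (1 - eq$x_star), eq$V_F_star, eq$V_D_star)
  } else {
    c(eq$x_star, eq$y_star, eq$V_F_star, eq$V_D_star)
  }
}

#' Spectral radius of the Jacobian at the interior equilibrium
#'
#' Linearizes the full coupled mean-field map — landscape densities plus the
#' belief variables `V_F` and `V_D` (dimension 4, or 5 with the
#' just-reforested density `w` under the reforestation incentive) — at the
#' interior equilibrium, using central finite differences, and returns the
#' largest eigenvalue modulus. A radius above 1 means the equilibrium is
#' locally unstable and trajectories near it fluctuate or cycle; with
#' `alpha = 0` beliefs are frozen and the system is always stable.
#'
#' @param params A [forest_params()] object.
#' @param h Finite-difference step (default `1e-6`).
#' @return The spectral radius, a single nonnegative number.
#' @examples
#' p <- forest_params(b = 5, c = 20, g = 7.5, alpha = 0.2, mu = 0.5,
#'                    governance = "yearly_incentive")
#' jacobian_spectral_radius(p) # > 1: locally unstable
#' @export
jacobian_spectral_radius <- function(params, h = 1e-6) {
  check_params(params)
  eq <- interior_equilibrium(params)
  if (!isTRUE(eq$exists)) {
    abort("No interior equilibrium found; cannot linearize.")
  }
  s0 <- equilibrium_state_vector(eq)
  # within 1e-6 of full (or zero) cover the map's division by 1 - x (or x)
  # makes a finite-difference linearization meaningless: treat as boundary
  if (eq$x_star <= 1e-6 || eq$x_star >= 1 - 1e-6) {
    abort("Equilibrium lies (numerically) on the landscape boundary; linearization is not reliable there.")
  }
  # shrink the step for the density coordinates so perturbed states stay
  # strictly inside the simplex (the map divides by x and by 1 - x)
  n_dens <- if (params$governance == "reforestation_incentive") 3L else 2L
  steps <- rep(h, length(s0))
  steps[seq_len(n_dens)] <- pmin(h, eq$x_star / 4, (1 - eq$x_star) / 4)
  J <- numeric_jacobian(function(s) meanfield_map(s, params), s0, steps)
  max(Mod(eigen(J, only.values = TRUE)$values))
}

numeric_jacobian <- function(f, s0, h) {
  n <- length(s0)
  h <- rep_len(h, n)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- s0; dn <- s0
    up[j] <- up[j] + h[j]
    dn[j] <- dn[j] - h[j]
    J[, j] <- (f(up) - f(dn)) / (2 * h[j])
  }
  J
}

#' Local stability across a grid of governance magnitudes
#'
#' Computes the interior equilibrium and its Jacobian spectral radius for
#' each value of `g`, holding the other parameters fixed. Useful for
#' locating the governance level at which an equilibrium loses local
#' stability.
#'
#' @param params A [forest_params()] template (its `g` is ignored).
#' @param g_values Numeric vector of governance magnitudes.
#' @return A tibble with columns `g`, `x_star`, `spectral_radius`, `stable`.
#' @examples
#' p <- forest_params(b = 5, c = 20, alpha = 0.2, mu = 0.5,
#'                    governance = "yearly_incentive")
#' stability_sweep(p, g_values = c(0, 2.5, 5, 7.5, 10))
#' @export
stability_sweep <- function(params, g_values = seq(0, 10, by = 0.25)) {
  check_params(params)
  purrr::map_dfr(g_values, function(g) {
    p <- forest_params(b = params$b, c = params$c, g = g,
                       alpha = params$alpha, mu = params$mu,
                       governance = params$governance)
    eq <- interior_equilibrium(p)
    rad <- if (eq$exists) jacobian_spectral_radius(p) else NA_real_
    tibble(g = g, x_star = eq$x_star, spectral_radius = rad,
           stable = !is.na(rad) & rad <= 1)
  })
}
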