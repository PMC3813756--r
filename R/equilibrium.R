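#' Interior equilibrium of the landscape dynamics
#'
#' For no governance, the yearly conservation incentive, and the one-time
#' deforestation penalty the interior equilibrium is available in closed
#' form. The equilibrium net gain of deforestation is
#' `delta_V* = c'_eff * mu - b'_eff`, where the yearly incentive replaces
#' `b'` by `b' + g'` and the penalty replaces `c'` by `c' - g'`; the
#' equilibrium deforestation rate is `r* = plogis(delta_V*)` and the
#' forested density `x* = mu / (mu + r*)`, equivalently a forested to
#' deforested ratio of `mu / r*`.
#'
#' Under the one-time reforestation incentive the experienced incentive
#' couples to the recovery flow (`pi_gF = g' w / x`, and `w/x = r` at any
#' fixed point), which makes the fixed-point condition
#' `r = plogis(c' mu - b' - g' r)` transcendental: no closed form exists and
#' the equilibrium is located by a damped fixed-point iteration, which may
#' legitimately fail; `exists` is `FALSE` in that case.
#'
#' @param params A [forest_params()] object.
#' @param tol Convergence tolerance of the damped search (reforestation
#'   mode).
#' @param max_iter Maximum damped-iteration count.
#' @return A `forest_equilibrium` object: a list with `x_star`, `y_star`,
#'   `r_star`, `delta_V_star`, `V_F_star`, `V_D_star`, `exists`, and the
#'   `params` used.
#' @examples
#' p <- forest_params(b = 5, c = 20, g = 3, alpha = 0.2, mu = 0.1,
#'                    governance = "yearly_incentive")
#' interior_equilibrium(p)$x_star
#' @export
interior_equilibrium <- function(params, tol = 1e-12, max_iter = 10000L) {
  check_params(params)
  if (params$governance == "reforestation_incentive") {
    # damped iteration on r = plogis(c'mu - b' - g' r); damping 0.2 keeps the
    # iteration a contraction for any g' (|d/dr| <= 0.8 + 0.2 * g'/4 damped)
    r <- 0.5
    lambda <- 0.2
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      r_new <- (1 - lambda) * r +
        lambda * plogis(params$c * params$mu - params$b - params$g * r)
      if (abs(r_new - r) < tol) {
        r <- r_new
        converged <- TRUE
        break
      }
      r <- r_new
    }
    if (!converged || !is.finite(r) || r < 0 || r > 1) {
      return(new_forest_equilibrium(NA_real_, NA_real_, NA_real_, NA_real_,
                                    NA_real_, NA_real_, FALSE, params))
    }
    delta_V <- params$c * params$mu - params$b - params$g * r
    x <- params$mu / (params$mu + r)
    return(new_forest_equilibrium(
      x, r * x, r, delta_V,
      V_F = params$b + params$g * r, V_D = params$c * params$mu,
      exists = TRUE, params = params
    ))
  }
  eff <- effective_utilities(params)
  delta_V <- eff$c * params$mu - eff$b
  r <- plogis(delta_V)
  x <- params$mu / (params$mu + r)
  new_forest_equilibrium(
    x, r * x, r, delta_V,
    V_F = eff$b, V_D = eff$c * params$mu,
    exists = TRUE, params = params
  )
}

new_forest_equilibrium <- function(x, y, r, delta_V, V_F, V_D, exists, params) {
  structure(
    list(x_star = x, y_star = y, r_star = r, delta_V_star = delta_V,
         V_F_star = V_F, V_D_star = V_D, exists = exists, params = params),
    class = "forest_equilibrium"
  )
}

#' @export
print.forest_equilibrium <- function(x, ...) {
  cat("<forest_equilibrium>\n")
  if (!x$exists) {
    cat("  no equilibrium found\n")
  } else {
    cat(sprintf("  x* = %.6f  y* = %.6f  r* = %.6f\n",
                x$x_star, x$y_star, x$r_star))
    cat(sprintf("  delta_V* = %.6f  (V_D* = %.4f, V_F* = %.4f)\n",
                x$delta_V_star, x$V_D_star, x$V_F_star))
  }
  invisible(x)
}

#' Net utility gain of deforestation at equilibrium
#'
#' Returns `delta_V* = c'_eff * mu - b'_eff` for the closed-form governance
#' modes. It is negative when the yearly incentive satisfies
#' `g' > c' mu - b'`, or when the penalty satisfies `(c' - g') mu < b'`; in
#' both cases deforesting is a losing proposition at equilibrium and forest
#' cover is high. The net gain increases with the recovery rate `mu`: faster
#' regrowth lets a landowner harvest timber more often.
#'
#' @param params A [forest_params()] object with a closed-form governance
#'   mode (not the reforestation incentive).
#' @return The equilibrium net gain, a single number.
#' @export
net_gain_at_equilibrium <- function(params) {
  check_params(params)
  if (params$governance == "reforestation_incentive") {
    abort("No closed-form equilibrium net gain under the reforestation incentive.")
  }
  eff <- effective_utilities(params)
  eff$c * params$mu - eff$b
}

#' Best (fully informed) choice about deforestation
#'
#' The long-run comparison a perfectly informed landowner would make:
#' deforest (1) when the one-time timber gain `c'` exceeds the long-run value
#' of keeping the parcel forested — `(b' + g')/mu` under the yearly incentive
#' (forgone services plus incentive over an expected recovery time of `1/mu`
#' years), or `g' + b'/mu` under the one-time penalty (forgone services plus
#' the fine). Conserve (0) otherwise; exact ties resolve to conserve.
#'
#' @param params A [forest_params()] object with a closed-form governance
#'   mode.
#' @return `1L` (deforest) or `0L` (conserve).
#' @export
best_choice <- function(params) {
  check_params(params)
  threshold <- switch(params$governance,
    none = params$b / params$mu,
    yearly_incentive = (params$b + params$g) / params$mu,
    deforestation_penalty = params$g + params$b / params$mu,
    reforestation_incentive =
      abort("No closed-form best choice under the reforestation incentive.")
  )
  if (params$c > threshold) 1L else 0L
}
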