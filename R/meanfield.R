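# One year of the density dynamics on plain numbers; shared by the exported
# step and the fast simulation loop.
mf_core <- function(x, y, w, beliefs, params, previous_experienced) {
  exp_u <- experienced_utilities(x, y, w, params, previous = previous_experienced)
  beliefs <- update_expected_utilities(beliefs, exp_u, params)
  r <- deforestation_probability(beliefs$V_D - beliefs$V_F)
  list(
    x = (1 - r) * x + params$mu * (1 - x),
    y = r * x,
    w = if (params$governance == "reforestation_incentive") params$mu * (1 - x) else 0,
    r = r, beliefs = beliefs, experienced = exp_u
  )
}

#' One year of the deterministic density dynamics
#'
#' Advances the mean-field (infinite-parcel) landscape by one year. Within a
#' year, beliefs are updated first from the landscape landowners can observe,
#' and transitions follow: a fraction `r` of forested parcels is deforested
#' and every deforested parcel recovers with probability `mu`, so
#' `x' = (1 - r) x + mu (1 - x)`, the just-deforested density becomes
#' `y' = r x`, and (reforestation mode) the just-reforested density becomes
#' `w' = mu (1 - x)`. A just-deforested parcel is eligible to recover the
#' following year like any other deforested parcel; this bookkeeping is the
#' one under which the equilibrium ratio of forested to deforested land is
#' `mu / r` and the governance substitution identities hold exactly.
#'
#' @param state Named list or vector with densities `x`, `y`, `w`.
#' @param beliefs Named list with `V_F`, `V_D`.
#' @param params A [forest_params()] object.
#' @param previous_experienced Optional previous experienced utilities for
#'   the empty-class carry-forward rule (see [experienced_utilities()]).
#' @return A list with elements `state` (new densities), `beliefs` (updated),
#'   and `record`: a one-row [tibble::tibble()] of the year's `x`, `y`, `w`
#'   (densities entering the year), `r`, `V_F`, `V_D`, `pi_F`, `pi_D`,
#'   `pi_gF`.
#' @seealso [simulate_meanfield()] to iterate over a horizon.
#' @export
step_densities <- function(state, beliefs, params, previous_experienced = NULL) {
  check_params(params)
  x <- state[["x"]]; y <- state[["y"]]; w <- state[["w"]] %||% 0
  tol <- 1e-12
  if (x < -tol || y < -tol || w < -tol || x > 1 + tol || x + y + w > 1 + 1e-9) {
    abort("Densities left [0, 1]: inconsistent state.")
  }

  res <- mf_core(x, y, w, beliefs, params, previous_experienced)
  record <- tibble(
    x = x, y = y, w = w, r = res$r,
    V_F = res$beliefs$V_F, V_D = res$beliefs$V_D,
    pi_F = res$experienced$pi_F, pi_D = res$experienced$pi_D,
    pi_gF = res$experienced$pi_gF
  )
  list(state = res[c("x", "y", "w")], beliefs = res$beliefs, record = record,
       experienced = res$experienced)
}

#' Simulate the deterministic mean-field dynamics
#'
#' Iterates [step_densities()] for `horizon` years. The dynamics are fully
#' deterministic: no random number generation is involved.
#'
#' @param params A [forest_params()] object.
#' @param horizon Number of years to simulate (>= 1).
#' @param init Named numeric vector or list with initial densities `x`, `y`
#'   and (optionally) `w`. Defaults to half-forested, nothing just cut or
#'   just recovered.
#' @param beliefs Optional initial beliefs (see [initial_beliefs()]).
#' @return A `forest_trajectory`: a tibble with one row per year and columns
#'   `t`, `x`, `y`, `w`, `r`, `V_F`, `V_D`, `pi_F`, `pi_D`, `pi_gF`. Row `t`
#'   holds the densities entering year `t`, the beliefs used that year, and
#'   the deforestation rate `r(t)` they imply. The parameters and engine are
#'   attached as attributes.
#' @examples
#' p <- forest_params(b = 5, c = 20, g = 2.5, alpha = 0.2, mu = 0.5,
#'                    governance = "yearly_incentive")
#' traj <- simulate_meanfield(p, horizon = 500)
#' tail(traj$x, 1) # converges near the closed-form equilibrium
#' @export
simulate_meanfield <- function(params, horizon = 2000,
                               init = c(x = 0.5, y = 0, w = 0),
                               beliefs = NULL) {
  check_params(params)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    abort("`horizon` must be a single integer >= 1.")
  }
  horizon <- as.integer(horizon)
  state <- list(x = init[["x"]], y = init[["y"]], w = init[["w"]] %||% 0)
  beliefs <- beliefs %||% initial_beliefs(params)

  cols <- c("x", "y", "w", "r", "V_F", "V_D", "pi_F", "pi_D", "pi_gF")
  out <- matrix(NA_real_, nrow = horizon, ncol = length(cols),
                dimnames = list(NULL, cols))
  exp_u <- NULL
  x <- state$x; y <- state$y; w <- state$w
  for (t in seq_len(horizon)) {
    res <- mf_core(x, y, w, beliefs, params, exp_u)
    out[t, ] <- c(x, y, w, res$r, res$beliefs$V_F, res$beliefs$V_D,
                  res$experienced$pi_F, res$experienced$pi_D,
                  res$experienced$pi_gF)
    x <- res$x; y <- res$y; w <- res$w
    beliefs <- res$beliefs
    exp_u <- res$experienced
  }
  state <- list(x = x, y = y, w = w)
  new_forest_trajectory(
    dplyr::bind_cols(tibble(t = seq_len(horizon)), as_tibble(out)),
    params = params, engine = "meanfield", seed = NA_integer_,
    final_state = state, final_beliefs = beliefs
  )
}

new_forest_trajectory <- function(data, params, engine, seed, final_state,
                                  final_beliefs) {
  structure(
    data,
    params = params, engine = engine, seed = seed,
    final_state = final_state, final_beliefs = final_beliefs,
    class = c("forest_trajectory", class(data))
  )
}

#' @export
print.forest_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<forest_trajectory: %s engine, %d years, %s>\n",
              attr(x, "engine"), nrow(x), format(p)))
  NextMethod()
}
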