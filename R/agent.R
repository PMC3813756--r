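# Parcel state codes used by the agent engine. "forested" and
# "just_reforested" are both forested land (a parcel that recovered this year
# already yields ecosystem services); "just_deforested" and "bare" are both
# deforested land. The two "just_*" classes exist so that the society-level
# densities y(t) and w(t) can be read off the landscape.
agent_states <- c("forested", "just_deforested", "bare", "just_reforested")

#' Initialize an agent landscape
#'
#' Creates a reproducible landscape of `n_parcels` land parcels with
#' `round(n_parcels * init_forest_fraction)` forested parcels placed at
#' seeded random positions; the rest start bare.
#'
#' @param n_parcels Number of parcels (>= 1).
#' @param init_forest_fraction Initial forested fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same landscape.
#' @return An `agent_landscape`: an integer vector of state codes with a
#'   `levels` attribute naming the four classes.
#' @examples
#' table(states(init_landscape(100, 0.5, seed = 1)))
#' @export
init_landscape <- function(n_parcels, init_forest_fraction = 0.5, seed = 1L) {
  if (!is.numeric(n_parcels) || length(n_parcels) != 1L || n_parcels < 1) {
    abort("`n_parcels` must be a single integer >= 1.")
  }
  if (init_forest_fraction < 0 || init_forest_fraction > 1) {
    abort("`init_forest_fraction` must lie in [0, 1].")
  }
  old_seed <- save_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  init_landscape_unseeded(n_parcels, init_forest_fraction)
}

#' Parcel states as a character vector
#'
#' @param landscape An `agent_landscape` from [init_landscape()].
#' @return Character vector of per-parcel states.
#' @export
states <- function(landscape) {
  attr(landscape, "levels")[unclass(landscape)]
}

landscape_densities <- function(landscape) {
  n <- length(landscape)
  counts <- tabulate(unclass(landscape), nbins = 4L)
  list(
    x = (counts[1L] + counts[4L]) / n, # forested incl. just-reforested
    y = counts[2L] / n,                # just-deforested
    w = counts[4L] / n                 # just-reforested
  )
}

#' One year of the stochastic agent dynamics
#'
#' Advances every parcel by one year: beliefs are first updated from the
#' landscape entering the year, each forested parcel is then independently
#' deforested with probability `r(t)` given by the logit rule, and each
#' deforested parcel independently recovers with probability `mu`. Draws are
#' made in fixed parcel order from the current RNG stream, so a seeded
#' simulation is bit-reproducible.
#'
#' @param landscape An `agent_landscape`.
#' @param beliefs Named list with `V_F`, `V_D`.
#' @param params A [forest_params()] object.
#' @param previous_experienced Optional previous experienced utilities for
#'   the empty-class carry-forward rule.
#' @return A list with `landscape`, `beliefs`, `record` (one-row tibble as in
#'   [step_densities()]) and `experienced`.
#' @export
step_agents <- function(landscape, beliefs, params, previous_experienced = NULL) {
  check_params(params)
  res <- agent_core(unclass(landscape), beliefs, params, previous_experienced)
  record <- tibble(
    x = res$x, y = res$y, w = res$w, r = res$r,
    V_F = res$beliefs$V_F, V_D = res$beliefs$V_D,
    pi_F = res$experienced$pi_F, pi_D = res$experienced$pi_D,
    pi_gF = res$experienced$pi_gF
  )
  list(
    landscape = structure(res$st, levels = agent_states,
                          class = "agent_landscape"),
    beliefs = res$beliefs, record = record, experienced = res$experienced
  )
}

# one agent year on a plain integer state vector; draws in fixed parcel order
agent_core <- function(st, beliefs, params, previous_experienced) {
  n <- length(st)
  counts <- tabulate(st, nbins = 4L)
  x <- (counts[1L] + counts[4L]) / n
  y <- counts[2L] / n
  w <- counts[4L] / n
  exp_u <- experienced_utilities(x, y, w, params,
                                 previous = previous_experienced)
  beliefs <- update_expected_utilities(beliefs, exp_u, params)
  r <- deforestation_probability(beliefs$V_D - beliefs$V_F)

  forested <- st == 1L | st == 4L
  draws <- runif(n)
  new_st <- integer(n)
  # forested parcels: deforested with probability r, else remain forested
  new_st[forested] <- 1L + (draws[forested] < r)
  # deforested parcels: recover (just-reforested) with probability mu
  new_st[!forested] <- 4L - (draws[!forested] >= params$mu)
  list(st = new_st, x = x, y = y, w = w, r = r, beliefs = beliefs,
       experienced = exp_u)
}

#' Simulate the stochastic agent-based engine
#'
#' Runs the N-parcel Markov chain for `horizon` years with a single seeded
#' RNG stream. For large `n_parcels` the yearly class densities approach the
#' deterministic mean-field dynamics of [simulate_meanfield()].
#'
#' @param params A [forest_params()] object.
#' @param n_parcels Number of land parcels.
#' @param horizon Number of years (>= 1).
#' @param seed Integer seed controlling every random draw.
#' @param init_forest_fraction Initial forested fraction.
#' @param beliefs Optional initial beliefs (see [initial_beliefs()]).
#' @return A `forest_trajectory` tibble as in [simulate_meanfield()], with
#'   `engine = "agent"` and the seed stored as an attribute.
#' @examples
#' p <- forest_params(b = 5, c = 20, alpha = 0.05, mu = 0.1)
#' traj <- simulate_agents(p, n_parcels = 500, horizon = 50, seed = 42)
#' @export
simulate_agents <- function(params, n_parcels = 10000, horizon = 1000,
                            seed = 1L, init_forest_fraction = 0.5,
                            beliefs = NULL) {
  check_params(params)
  if (horizon < 1) abort("`horizon` must be >= 1.")
  horizon <- as.integer(horizon)

  old_seed <- save_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  landscape <- init_landscape_unseeded(n_parcels, init_forest_fraction)
  beliefs <- beliefs %||% initial_beliefs(params)

  cols <- c("x", "y", "w", "r", "V_F", "V_D", "pi_F", "pi_D", "pi_gF")
  out <- matrix(NA_real_, nrow = horizon, ncol = length(cols),
                dimnames = list(NULL, cols))
  exp_u <- NULL
  st <- unclass(landscape)
  for (t in seq_len(horizon)) {
    res <- agent_core(st, beliefs, params, exp_u)
    out[t, ] <- c(res$x, res$y, res$w, res$r, res$beliefs$V_F,
                  res$beliefs$V_D, res$experienced$pi_F,
                  res$experienced$pi_D, res$experienced$pi_gF)
    st <- res$st
    beliefs <- res$beliefs
    exp_u <- res$experienced
  }
  final <- landscape_densities(
    structure(st, levels = agent_states, class = "agent_landscape"))
  new_forest_trajectory(
    dplyr::bind_cols(tibble(t = seq_len(horizon)), as_tibble(out)),
    params = params, engine = "agent", seed = as.integer(seed),
    final_state = final, final_beliefs = beliefs
  )
}

# landscape initialization drawing from the current RNG stream
init_landscape_unseeded <- function(n_parcels, init_forest_fraction) {
  n_parcels <- as.integer(n_parcels)
  n_forest <- as.integer(round(n_parcels * init_forest_fraction))
  st <- rep(3L, n_parcels)
  if (n_forest > 0) st[sample.int(n_parcels, n_forest)] <- 1L
  structure(st, levels = agent_states, class = "agent_landscape")
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
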