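#' Initial expected utilities
#'
#' A neutral "informed" starting belief: the expected utility of keeping a
#' parcel forested is the value of a full recovery cycle of ecosystem
#' services, `b'/mu`, and the expected utility of deforesting is the timber
#' gain `c'`. The model specifies no canonical initial beliefs; these
#' defaults can be overridden.
#'
#' @param params A [forest_params()] object.
#' @param V_F,V_D Optional numeric overrides.
#' @return A named list with components `V_F` and `V_D`.
#' @examples
#' initial_beliefs(forest_params(b = 5, c = 20, mu = 0.1))
#' @export
initial_beliefs <- function(params, V_F = NULL, V_D = NULL) {
  check_params(params)
  list(
    V_F = V_F %||% params$b / max(params$mu, 1e-9),
    V_D = V_D %||% params$c
  )
}

#' Update expected utilities by social learning with forgetting
#'
#' Exponential smoothing of beliefs on the current year's society-averaged
#' experienced utilities, with weight `alpha` on the new information:
#' `V(t) = (1 - alpha) V(t-1) + alpha * pi(t)`. Governance enters on the side
#' of the land state it attaches to: the yearly and reforestation incentives
#' augment the forested-side experienced term (`pi_F + pi_gF`), while the
#' deforestation penalty reduces the deforested-side term (`pi_D - pi_gF`).
#'
#' With `alpha = 0` beliefs are time-invariant; with `alpha = 1` they equal
#' the current experienced terms exactly.
#'
#' @param beliefs Named list with `V_F`, `V_D` (see [initial_beliefs()]).
#' @param experienced Named list with `pi_F`, `pi_D`, `pi_gF`
#'   (see [experienced_utilities()]).
#' @param params A [forest_params()] object.
#' @return Updated beliefs: a named list with `V_F` and `V_D`.
#' @examples
#' p <- forest_params(alpha = 0.5)
#' update_expected_utilities(list(V_F = 0, V_D = 0),
#'                           list(pi_F = 10, pi_D = 10, pi_gF = 0), p)
#' @export
update_expected_utilities <- function(beliefs, experienced, params) {
  check_params(params)
  a <- params$alpha
  forested_side <- experienced$pi_F +
    if (params$governance %in% c("yearly_incentive", "reforestation_incentive"))
      experienced$pi_gF else 0
  deforested_side <- experienced$pi_D -
    if (params$governance == "deforestation_penalty") experienced$pi_gF else 0
  list(
    V_F = (1 - a) * beliefs$V_F + a * forested_side,
    V_D = (1 - a) * beliefs$V_D + a * deforested_side
  )
}

#' Probability that a forested parcel is deforested
#'
#' The logit (logistic) choice rule on the net expected gain of deforestation
#' `delta_V = V_D - V_F`:
#' `r = 1 / (1 + exp(-delta_V))`. The rule is monotone nondecreasing in
#' `delta_V`, equals 1/2 at indifference, and approaches 0 or 1 in the
#' deterministic-decision limits `delta_V -> -Inf` / `+Inf`. The underlying
#' stochasticity constant `beta` is absorbed into the rescaled utilities, so
#' no temperature parameter appears here. Evaluated via [stats::plogis()],
#' which is numerically stable for very large `|delta_V|`.
#'
#' @param delta_V Numeric vector of net gains `V_D - V_F` (finite).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' deforestation_probability(c(-Inf, 0, 2, Inf))
#' @export
deforestation_probability <- function(delta_V) {
  if (!is.numeric(delta_V) || anyNA(delta_V)) {
    abort("`delta_V` must be numeric with no missing values.")
  }
  plogis(delta_V)
}
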