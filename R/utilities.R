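#' Per-parcel events
#'
#' The four things that can happen to a land parcel in a year: it stays
#' forested, it is deforested this year, it stays bare, or it recovers
#' (reforests) this year. Exactly one applies to each parcel each year.
#'
#' @format A character vector of the four event names.
#' @export
parcel_events <- c("stay_forested", "deforest_now", "stay_bare", "reforest_now")

check_event <- function(event) {
  if (!is.character(event) || !all(event %in% parcel_events)) {
    abort(sprintf("`event` must be one of: %s.",
                  paste(parcel_events, collapse = ", ")))
  }
  event
}

#' Actual utility received for a parcel event
#'
#' The realized (not expected) utility a landowner receives in a year, given
#' what happened on the parcel: `b'` for a year spent forested, `c'` once at
#' the moment of deforestation, and 0 for bare land, which yields no income.
#' A parcel that reforests this year is forested this year and earns `b'`;
#' any reforestation bonus is a governance payment and is accounted for by
#' [governance_utility()], so with `g' = 0` every mode reduces exactly to the
#' base model.
#'
#' @param event Character vector of events, see [parcel_events].
#' @param params A [forest_params()] object.
#' @return Numeric vector of utilities, one per event.
#' @examples
#' p <- forest_params(b = 5, c = 20)
#' actual_utility(c("stay_forested", "deforest_now", "stay_bare"), p)
#' @export
actual_utility <- function(event, params) {
  check_params(params)
  check_event(event)
  unname(c(stay_forested = params$b, deforest_now = params$c,
           stay_bare = 0, reforest_now = params$b)[event])
}

#' Governance utility received for a parcel event
#'
#' The payment (or fine) issued by the governing body for a parcel event
#' under the active governance mode: a yearly incentive pays `g'` for every
#' year a parcel stays forested (including the year it reforests); the
#' one-time penalty charges `g'` at the moment of deforestation; the one-time
#' reforestation incentive pays `g'` at the moment of recovery. With no
#' governance (or `g' = 0`) every event yields 0.
#'
#' @inheritParams actual_utility
#' @return Numeric vector of governance utilities (negative for penalties).
#' @examples
#' p <- forest_params(g = 7.5, governance = "yearly_incentive")
#' governance_utility(c("stay_forested", "deforest_now"), p)
#' @export
governance_utility <- function(event, params) {
  check_params(params)
  check_event(event)
  tab <- switch(params$governance,
    none = c(stay_forested = 0, deforest_now = 0, stay_bare = 0, reforest_now = 0),
    yearly_incentive = c(stay_forested = params$g, deforest_now = 0,
                         stay_bare = 0, reforest_now = params$g),
    deforestation_penalty = c(stay_forested = 0, deforest_now = -params$g,
                              stay_bare = 0, reforest_now = 0),
    reforestation_incentive = c(stay_forested = 0, deforest_now = 0,
                                stay_bare = 0, reforest_now = params$g)
  )
  unname(tab[event])
}

#' Society-averaged experienced utilities
#'
#' What landowners learn from each other at the end of a year: the average
#' realized utility over parcels in the forested class (`pi_F`), over parcels
#' in the deforested class (`pi_D`), and the average experienced governance
#' term (`pi_gF`). Just-deforested parcels contribute `c'` to the deforested
#' class; parcels bare for longer contribute 0, so
#' `pi_D = c' * y / (1 - x)`. Every forested parcel earns `b'`, so
#' `pi_F = b'`. The governance term is averaged over the class holding the
#' land state the instrument attaches to: `g'` per forested parcel under the
#' yearly incentive, `g' * y / (1 - x)` over the deforested class under the
#' penalty, and `g' * w / x` over the forested class under the reforestation
#' incentive (only the just-reforested fraction `w` received the payment).
#'
#' @param x Density of forested parcels in `[0, 1]`.
#' @param y Density of just-deforested parcels (deforested this year).
#' @param w Density of just-reforested parcels (reforestation mode; 0
#'   otherwise).
#' @param params A [forest_params()] object.
#' @param previous Optional named list (or one-row tibble) with the previous
#'   year's `pi_F`, `pi_D`, `pi_gF`. When a class is empty (no forested or no
#'   deforested parcels) its average is undefined; the previous value is
#'   carried forward. Defaults of `b'`, 0 and 0 are used if no previous
#'   values are supplied.
#' @return A named list with components `pi_F`, `pi_D`, `pi_gF`.
#' @examples
#' p <- forest_params(b = 5, c = 20)
#' experienced_utilities(x = 0.5, y = 0.25, w = 0, params = p)
#' @export
experienced_utilities <- function(x, y, w = 0, params, previous = NULL) {
  check_params(params)
  if (any(!is.finite(c(x, y, w))) || x < -1e-12 || y < -1e-12 || w < -1e-12 ||
      x > 1 + 1e-12 || x + y > 1 + 1e-9) {
    abort("Densities must satisfy 0 <= x, y, w and x + y <= 1.")
  }
  prev <- list(pi_F = params$b, pi_D = 0, pi_gF = 0)
  if (!is.null(previous)) for (nm in names(prev)) {
    if (!is.null(previous[[nm]])) prev[[nm]] <- previous[[nm]]
  }

  forest_empty <- x <= 0
  deforest_empty <- (1 - x) <= 0

  pi_F <- if (forest_empty) prev$pi_F else params$b
  pi_D <- if (deforest_empty) prev$pi_D else params$c * y / (1 - x)
  pi_gF <- switch(params$governance,
    none = 0,
    yearly_incentive = if (forest_empty) prev$pi_gF else params$g,
    deforestation_penalty =
      if (deforest_empty) prev$pi_gF else params$g * y / (1 - x),
    reforestation_incentive =
      if (forest_empty) prev$pi_gF else params$g * w / x
  )
  list(pi_F = pi_F, pi_D = pi_D, pi_gF = pi_gF)
}
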