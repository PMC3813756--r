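#' Model parameters for the land-use decision model
#'
#' Bundles the five rescaled parameters of the coupled human-environment
#' Markov chain together with the governance strategy in force. All utilities
#' are dimensionless: the original decision-stochasticity constant `beta` of
#' the logit choice rule is absorbed into `b`, `c` and `g` by rescaling
#' (`b' = b*beta` and so on), so it does not appear as a separate parameter.
#'
#' @param b Nonnegative scalar. Rescaled yearly utility of a forested parcel
#'   (value of its ecosystem services to the owner), `b'`.
#' @param c Nonnegative scalar. Rescaled one-time gain from deforesting a
#'   parcel (timber revenue), `c'`.
#' @param g Nonnegative scalar. Rescaled magnitude of the governance
#'   instrument, `g'`. Its meaning depends on `governance`: a payment per
#'   forested year, a one-time fine at deforestation, or a one-time payment
#'   at reforestation.
#' @param alpha Forgetting coefficient in `[0, 1]`: the weight placed on the
#'   current year's socially shared experienced utilities when landowners
#'   update their expected utilities. `alpha = 0` means beliefs never change
#'   (only prior knowledge counts); `alpha = 1` means decisions use only the
#'   current year's information.
#' @param mu Forest recovery rate in `(0, 1]`: the yearly probability that a
#'   deforested parcel returns to forest, so `1/mu` is the expected recovery
#'   time in years.
#' @param governance One of `"none"`, `"yearly_incentive"`,
#'   `"deforestation_penalty"`, `"reforestation_incentive"`.
#'
#' @return An object of class `forest_params`: a named list with the six
#'   fields above.
#'
#' @details `governance = "none"` is identical, event by event, to any
#'   governance mode with `g = 0`.
#'
#' @examples
#' forest_params(b = 5, c = 20, g = 7.5, alpha = 0.2, mu = 0.5,
#'               governance = "yearly_incentive")
#' @export
forest_params <- function(b = 5, c = 20, g = 0, alpha = 0.2, mu = 0.1,
                          governance = c("none", "yearly_incentive",
                                         "deforestation_penalty",
                                         "reforestation_incentive")) {
  governance <- match.arg(governance)
  for (nm in c("b", "c", "g", "alpha", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (b < 0 || c < 0 || g < 0) abort("`b`, `c` and `g` must be nonnegative.")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (mu <= 0 || mu > 1) abort("`mu` must lie in (0, 1].")
  structure(
    list(b = b, c = c, g = g, alpha = alpha, mu = mu, governance = governance),
    class = "forest_params"
  )
}

#' @export
print.forest_params <- function(x, ...) {
  cat("<forest_params>\n")
  cat(sprintf("  b' = %g, c' = %g, g' = %g\n", x$b, x$c, x$g))
  cat(sprintf("  alpha = %g (forgetting), mu = %g (recovery)\n", x$alpha, x$mu))
  cat(sprintf("  governance: %s\n", x$governance))
  invisible(x)
}

#' @export
format.forest_params <- function(x, ...) {
  sprintf("forest_params(b=%g, c=%g, g=%g, alpha=%g, mu=%g, %s)",
          x$b, x$c, x$g, x$alpha, x$mu, x$governance)
}

is_forest_params <- function(x) inherits(x, "forest_params")

check_params <- function(params) {
  if (!is_forest_params(params)) {
    abort("`params` must be a `forest_params` object (see `forest_params()`).")
  }
  params
}

# Effective (b', c') after folding the governance term into the mode where the
# substitution identity holds exactly at equilibrium: the yearly incentive acts
# like b' -> b' + g', the one-time penalty like c' -> c' - g'.
effective_utilities <- function(params) {
  b_eff <- params$b + if (params$governance == "yearly_incentive") params$g else 0
  c_eff <- params$c - if (params$governance == "deforestation_penalty") params$g else 0
  list(b = b_eff, c = c_eff)
}
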