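#' Classify a trajectory into one of four qualitative landscape outcomes
#'
#' The model produces four qualitative outcomes: a stationary-forested
#' landscape, a stationary-deforested landscape (converged below 50% forest
#' cover), an unstable landscape fluctuating aperiodically near the
#' equilibrium, and a cyclic-forested landscape with large synchronized
#' deforestation cycles. The classification is computed on the post-burn-in
#' half of the trajectory: a run has converged when the forest cover `x`
#' varies by less than `convergence_tol` over the final
#' `convergence_window` years; a non-converged run is cyclic when its
#' amplitude is at least `amplitude_threshold` and an autocorrelation peak
#' identifies a dominant period, and unstable-fluctuating otherwise. The
#' numeric thresholds are declared package conventions; the qualitative
#' taxonomy itself gives no numbers except the 50% cover criterion.
#'
#' @param traj A `forest_trajectory`, or any data frame with columns `t` and
#'   `x`.
#' @param params Optional [forest_params()]; defaults to the trajectory's
#'   attached parameters. When available and an interior equilibrium exists,
#'   its Jacobian spectral radius is included as a diagnostic.
#' @param convergence_window Years over which near-constancy defines
#'   convergence (default 200).
#' @param convergence_tol Maximum peak-to-trough variation of `x` counted as
#'   converged (default `1e-6`).
#' @param amplitude_threshold Minimum post-burn-in amplitude for a cyclic
#'   classification (default 0.05).
#' @return A `regime_report`: a list with `regime` (one of
#'   `"stationary_forested"`, `"stationary_deforested"`,
#'   `"unstable_fluctuating"`, `"cyclic_forested"`), `mean_cover`,
#'   `amplitude`, `dominant_period`, `spectral_radius`, and `converged`.
#' @examples
#' p <- forest_params(b = 5, c = 20, g = 2.5, alpha = 0.2, mu = 0.5,
#'                    governance = "yearly_incentive")
#' classify_regime(simulate_meanfield(p, horizon = 1000))$regime
#' @export
classify_regime <- function(traj, params = NULL,
                            convergence_window = 200,
                            convergence_tol = 1e-6,
                            amplitude_threshold = 0.05) {
  if (!is.data.frame(traj) || !all(c("t", "x") %in% names(traj))) {
    abort("`traj` must be a data frame with columns `t` and `x`.")
  }
  n <- nrow(traj)
  burn_in <- floor(n / 2)
  if (n - burn_in < convergence_window) {
    abort(sprintf(
      "Trajectory too short to classify: need at least %d post-burn-in years.",
      convergence_window))
  }
  params <- params %||% attr(traj, "params")

  x_window <- traj$x[(burn_in + 1):n]
  x_tail <- traj$x[(n - convergence_window + 1):n]
  mean_cover <- mean(x_window)
  amplitude <- max(x_window) - min(x_window)
  converged <- (max(x_tail) - min(x_tail)) < convergence_tol

  dominant_period <- if (!converged) dominant_period(x_window) else NA_real_

  regime <- if (converged) {
    if (mean_cover >= 0.5) "stationary_forested" else "stationary_deforested"
  } else if (amplitude >= amplitude_threshold && !is.na(dominant_period)) {
    "cyclic_forested"
  } else {
    "unstable_fluctuating"
  }

  spectral_radius <- NA_real_
  if (!is.null(params)) {
    eq <- interior_equilibrium(params)
    if (isTRUE(eq$exists) && eq$x_star > 0 && eq$x_star < 1) {
      spectral_radius <- tryCatch(jacobian_spectral_radius(params),
                                  error = function(e) NA_real_)
    }
  }

  structure(
    list(regime = regime, mean_cover = mean_cover, amplitude = amplitude,
         dominant_period = dominant_period, spectral_radius = spectral_radius,
         converged = converged, n_years = n, burn_in = burn_in),
    class = "regime_report"
  )
}

# Dominant oscillation period from the first interior peak of the
# autocorrelation function; robust for square-wave-like relaxation cycles.
# Returns NA when no convincing peak exists (aperiodic fluctuation).
dominant_period <- function(x, min_acf = 0.1) {
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 2L, 1000L)
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  if (length(rho) < 3) return(NA_real_)
  interior <- 2:(length(rho) - 1)
  peaks <- interior[rho[interior] > rho[interior - 1] &
                    rho[interior] >= rho[interior + 1] &
                    rho[interior] > min_acf]
  if (length(peaks) == 0) return(NA_real_)
  as.numeric(peaks[which.max(rho[peaks])])
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  cat(sprintf("  regime: %s\n", x$regime))
  cat(sprintf("  mean cover %.4f, amplitude %.4f, converged: %s\n",
              x$mean_cover, x$amplitude, x$converged))
  if (!is.na(x$dominant_period)) {
    cat(sprintf("  dominant period: %g years\n", x$dominant_period))
  }
  if (!is.na(x$spectral_radius)) {
    cat(sprintf("  Jacobian spectral radius: %.4f\n", x$spectral_radius))
  }
  invisible(x)
}
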