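# Scenario presets reproducing the published parameter regimes. Time-series
# presets share b' = 5, c' = 20 and cross three forgetting coefficients with
# two recovery rates; equilibrium-map presets sweep mu for five governance
# levels at large, intermediate and small utility scales. The governance
# levels span 0-50% of the deforestation gain c'.
preset_table <- function() {
  ts_panels <- tibble(
    panel = c("A", "B", "C", "D", "E", "F"),
    alpha = c(0.05, 0.2, 0.9, 0.05, 0.2, 0.9),
    mu = c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5)
  )
  ts <- purrr::pmap_dfr(
    list(prefix = c("fig3", "fig5", "fig6"),
         governance = c("yearly_incentive", "deforestation_penalty",
                        "reforestation_incentive")),
    function(prefix, governance) {
      dplyr::mutate(ts_panels,
        name = paste0(prefix, .data$panel),
        kind = "timeseries", governance = governance,
        b = 5, c = 20, g_levels = list(c(0, 2.5, 5, 7.5, 10)))
    }
  )
  eq_scales <- tibble(
    panel = c("A", "B", "C"),
    b = c(5000, 5, 0.0005),
    c = c(20000, 20, 0.002),
    g_levels = list(c(0, 2500, 5000, 7500, 10000),
                    c(0, 2.5, 5, 7.5, 10),
                    c(0, 0.00025, 0.0005, 0.00075, 0.001))
  )
  eq <- purrr::pmap_dfr(
    list(prefix = c("fig2", "fig4"),
         governance = c("yearly_incentive", "deforestation_penalty")),
    function(prefix, governance) {
      dplyr::mutate(eq_scales,
        name = paste0(prefix, .data$panel),
        kind = "equilibrium", governance = governance,
        alpha = 0.2, mu = NA_real_)
    }
  )
  dplyr::select(
    dplyr::bind_rows(ts, eq),
    "name", "kind", "governance", "b", "c", "alpha", "mu", "g_levels"
  )
}

#' List the built-in scenario presets
#'
#' Named parameter regimes covering every published figure panel: `fig3A`
#' through `fig3F` (yearly conservation incentive time series), `fig5A`-`F`
#' (one-time deforestation penalty), `fig6A`-`F` (one-time reforestation
#' incentive), and the equilibrium-versus-recovery-rate maps `fig2A`-`C`
#' (yearly incentive) and `fig4A`-`C` (penalty) at large, intermediate and
#' small utility scales. Time-series presets vary the forgetting coefficient
#' (`alpha` = 0.05, 0.2, 0.9) against the recovery rate (`mu` = 0.1, 0.5);
#' every preset carries five governance levels spanning 0-50% of the
#' deforestation gain.
#'
#' @return A tibble with one row per preset: `name`, `kind`, `governance`,
#'   `b`, `c`, `alpha`, `mu` and the `g_levels` list-column.
#' @examples
#' scenario_presets()
#' @export
scenario_presets <- function() preset_table()

#' Retrieve one preset as parameters or a sweep grid
#'
#' @param name Preset name, e.g. `"fig3E"` (see [scenario_presets()]).
#' @param g Governance magnitude for time-series presets; defaults to the
#'   first of the preset's levels. Ignored for equilibrium presets.
#' @return For a time-series preset, a [forest_params()] object. For an
#'   equilibrium preset, a list with `defaults` (a [forest_params()]
#'   template) and `grid` (a tibble crossing `mu` in `[0.01, 0.5]` with the
#'   preset's governance levels).
#' @examples
#' preset_params("fig3E", g = 7.5)
#' @export
preset_params <- function(name, g = NULL) {
  tab <- preset_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown preset '%s'; see scenario_presets().", name))
  }
  levels <- row$g_levels[[1]]
  if (row$kind == "timeseries") {
    g <- g %||% levels[1]
    if (!g %in% levels) {
      warn(sprintf("g = %g is not one of preset '%s' levels (%s).",
                   g, name, paste(levels, collapse = ", ")))
    }
    forest_params(b = row$b, c = row$c, g = g, alpha = row$alpha,
                  mu = row$mu, governance = row$governance)
  } else {
    list(
      defaults = forest_params(b = row$b, c = row$c, g = levels[1],
                               alpha = row$alpha, mu = 0.1,
                               governance = row$governance),
      grid = tidyr::expand_grid(mu = seq(0.01, 0.5, by = 0.01), g = levels)
    )
  }
}
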