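# shared fixtures: the published parameter regime b' = 5, c' = 20
yearly_params <- function(g = 0, alpha = 0.2, mu = 0.5) {
  forest_params(b = 5, c = 20, g = g, alpha = alpha, mu = mu,
                governance = "yearly_incentive")
}

penalty_params <- function(g = 0, alpha = 0.2, mu = 0.5) {
  forest_params(b = 5, c = 20, g = g, alpha = alpha, mu = mu,
                governance = "deforestation_penalty")
}

reforest_params <- function(g = 0, alpha = 0.2, mu = 0.1) {
  forest_params(b = 5, c = 20, g = g, alpha = alpha, mu = mu,
                governance = "reforestation_incentive")
}

# beliefs that pin the deforestation probability to `r` exactly when used
# with alpha = 0 (beliefs never move)
beliefs_for_rate <- function(r) {
  list(V_F = 0, V_D = log(r / (1 - r)))
}

# draw a random valid parameter set (used by property-style tests)
random_params <- function(governance = c("none", "yearly_incentive",
                                         "deforestation_penalty")) {
  forest_params(
    b = runif(1, 0.5, 20), c = runif(1, 5, 40), g = runif(1, 0, 10),
    alpha = runif(1, 0.05, 0.95), mu = runif(1, 0.05, 0.5),
    governance = sample(governance, 1)
  )
}
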