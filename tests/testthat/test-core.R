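test_that("actual utility pays b' for forested years, c' at deforestation, 0 for bare land", {
  p <- forest_params(b = 5, c = 20)
  expect_equal(actual_utility("stay_forested", p), 5)
  expect_equal(actual_utility("deforest_now", p), 20)
  expect_equal(actual_utility("stay_bare", p), 0)
  expect_equal(actual_utility("reforest_now", p), 5) # forested that year
  expect_error(actual_utility("harvest", p), "event")
})

test_that("governance utility matches the three instruments", {
  yearly <- forest_params(g = 7.5, governance = "yearly_incentive")
  expect_equal(governance_utility("stay_forested", yearly), 7.5)
  expect_equal(governance_utility("deforest_now", yearly), 0)
  expect_equal(governance_utility("reforest_now", yearly), 7.5)

  pen <- forest_params(g = 5, governance = "deforestation_penalty")
  expect_equal(governance_utility("deforest_now", pen), -5)
  expect_equal(governance_utility("stay_forested", pen), 0)

  refo <- forest_params(g = 4, governance = "reforestation_incentive")
  expect_equal(governance_utility("reforest_now", refo), 4)
  expect_equal(governance_utility("stay_forested", refo), 0)

  none <- forest_params(governance = "none")
  expect_equal(governance_utility(parcel_events, none), rep(0, 4))
})

test_that("experienced utilities equal brute-force class averages over an explicit landscape", {
  p <- forest_params(b = 5, c = 20)
  # 1000 parcels: 500 forested, 250 just-deforested, 250 long-bare
  events <- rep(c("stay_forested", "deforest_now", "stay_bare"),
                times = c(500, 250, 250))
  u <- actual_utility(events, p)
  forested <- events == "stay_forested"
  # parcels deforested this year were forested when the year began; the
  # deforested class they join averages their c' against older bare parcels
  deforested <- !forested
  oracle_pi_F <- mean(u[forested])
  oracle_pi_D <- mean(u[deforested])

  got <- experienced_utilities(x = 0.5, y = 0.25, w = 0, params = p)
  expect_equal(got$pi_F, oracle_pi_F)
  expect_equal(got$pi_D, oracle_pi_D)
  expect_equal(got$pi_D, 10) # c' * y / (1 - x) = 20 * 0.25 / 0.5
})

test_that("experienced utilities handle degenerate class structure", {
  p <- forest_params(b = 5, c = 20)
  expect_equal(experienced_utilities(1, 0, 0, p)$pi_F, 5) # all forested
  expect_equal(experienced_utilities(0.6, 0, 0, p)$pi_D, 0) # bare only
  # empty deforested class: previous experienced value carries forward
  carried <- experienced_utilities(1, 0, 0, p,
                                   previous = list(pi_D = 7.3))
  expect_equal(carried$pi_D, 7.3)
  # empty forested class carries pi_F forward
  carried_f <- experienced_utilities(0, 0.2, 0, p,
                                     previous = list(pi_F = 2.2))
  expect_equal(carried_f$pi_F, 2.2)
  expect_error(experienced_utilities(1.2, 0, 0, p), "Densities")
})

test_that("experienced governance term averages over the class holding the instrument", {
  yearly <- forest_params(g = 7.5, governance = "yearly_incentive")
  expect_equal(experienced_utilities(0.4, 0.1, 0, yearly)$pi_gF, 7.5)

  pen <- forest_params(g = 5, governance = "deforestation_penalty")
  expect_equal(experienced_utilities(0.5, 0.25, 0, pen)$pi_gF,
               5 * 0.25 / 0.5)

  refo <- forest_params(g = 4, governance = "reforestation_incentive")
  expect_equal(experienced_utilities(0.5, 0.1, 0.05, refo)$pi_gF,
               4 * 0.05 / 0.5)
})

test_that("belief update is exponential smoothing with weight alpha on current information", {
  # alpha = 0.5, prior 0, experienced 10 -> 5 (one hand-iterated step)
  p <- forest_params(alpha = 0.5)
  out <- update_expected_utilities(list(V_F = 0, V_D = 0),
                                   list(pi_F = 10, pi_D = 10, pi_gF = 0), p)
  expect_equal(out$V_F, 5)
  expect_equal(out$V_D, 5)

  # alpha = 1: beliefs are the current experienced terms exactly
  p1 <- forest_params(alpha = 1)
  out1 <- update_expected_utilities(list(V_F = 99, V_D = -4),
                                    list(pi_F = 5, pi_D = 12, pi_gF = 0), p1)
  expect_equal(out1$V_F, 5)
  expect_equal(out1$V_D, 12)

  # alpha = 0: beliefs never move, however many years pass
  p0 <- forest_params(alpha = 0)
  beliefs <- list(V_F = 3, V_D = 9)
  for (i in 1:25) {
    beliefs <- update_expected_utilities(
      beliefs, list(pi_F = runif(1, 0, 50), pi_D = runif(1, 0, 50),
                    pi_gF = runif(1, 0, 10)), p0)
  }
  expect_equal(beliefs, list(V_F = 3, V_D = 9))
})

test_that("governance enters beliefs on the side of the land state it attaches to", {
  exp_u <- list(pi_F = 5, pi_D = 10, pi_gF = 2)
  prior <- list(V_F = 0, V_D = 0)

  yearly <- forest_params(alpha = 1, governance = "yearly_incentive")
  expect_equal(update_expected_utilities(prior, exp_u, yearly),
               list(V_F = 7, V_D = 10))

  pen <- forest_params(alpha = 1, governance = "deforestation_penalty")
  expect_equal(update_expected_utilities(prior, exp_u, pen),
               list(V_F = 5, V_D = 8))

  refo <- forest_params(alpha = 1, governance = "reforestation_incentive")
  expect_equal(update_expected_utilities(prior, exp_u, refo),
               list(V_F = 7, V_D = 10))
})

test_that("deforestation probability is the logistic choice rule", {
  expect_equal(deforestation_probability(0), 0.5)
  # frozen against an independent arbitrary-precision evaluation of
  # 1 / (1 + exp(-dV))
  expect_equal(deforestation_probability(2), 0.880797077977882444,
               tolerance = 1e-15)
  expect_equal(deforestation_probability(0.5), 0.622459331201854565,
               tolerance = 1e-15)
  expect_equal(deforestation_probability(-3.7), 0.024127021417669197,
               tolerance = 1e-15)
  # deterministic-decision limits
  expect_equal(deforestation_probability(c(-Inf, Inf)), c(0, 1))
  # numerically stable for very large |dV|
  expect_equal(deforestation_probability(c(-1e4, 1e4)), c(0, 1))
  expect_false(anyNA(deforestation_probability(c(-1e8, 1e8))))
  expect_error(deforestation_probability(NA_real_), "missing")
})

test_that("deforestation probability is monotone and bounded on random inputs", {
  set.seed(42)
  dv <- sort(runif(200, -50, 50))
  r <- deforestation_probability(dv)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(diff(r) >= 0))
})
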