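test_that("landscape initialization is exact and seeded", {
  l <- init_landscape(100, 0.5, seed = 1)
  expect_equal(sum(states(l) == "forested"), 50)
  expect_true(all(states(init_landscape(10, 1.0, seed = 3)) == "forested"))
  expect_equal(init_landscape(1000, 0.3, seed = 7),
               init_landscape(1000, 0.3, seed = 7))
  expect_error(init_landscape(0), "n_parcels")
  expect_error(init_landscape(10, 1.5), "init_forest_fraction")
})

test_that("a fully forested landscape with r = 0 is absorbing; r = 1 deforests everything", {
  p <- forest_params(b = 5, c = 20, alpha = 0, mu = 0.3)
  l <- init_landscape(200, 1.0, seed = 1)
  # beliefs make deforestation impossible (plogis underflows to 0)
  frozen <- list(V_F = 1e9, V_D = 0)
  stp <- step_agents(l, frozen, p)
  expect_true(all(states(stp$landscape) == "forested"))
  expect_equal(stp$record$r, 0)

  certain <- list(V_F = 0, V_D = 1e9)
  stp2 <- step_agents(l, certain, p)
  expect_true(all(states(stp2$landscape) == "just_deforested"))
})

test_that("one-step transition counts match binomial means", {
  # alpha = 0 with pinned beliefs fixes r; expected transitions are then
  # Binomial(n_forested, r) and Binomial(n_deforested, mu) draws
  r_target <- 0.3
  p <- forest_params(b = 5, c = 20, alpha = 0, mu = 0.2)
  beliefs <- beliefs_for_rate(r_target)
  n <- 500
  l <- init_landscape(n, 0.6, seed = 11)
  n_forest <- sum(states(l) == "forested")
  n_bare <- n - n_forest

  set.seed(202)
  reps <- 4000
  defo <- refo <- numeric(reps)
  for (i in seq_len(reps)) {
    stp <- step_agents(l, beliefs, p)
    s <- states(stp$landscape)
    defo[i] <- sum(s == "just_deforested")
    refo[i] <- sum(s == "just_reforested")
  }
  se_defo <- sqrt(n_forest * r_target * (1 - r_target) / reps)
  se_refo <- sqrt(n_bare * p$mu * (1 - p$mu) / reps)
  expect_lt(abs(mean(defo) - n_forest * r_target), 3 * se_defo)
  expect_lt(abs(mean(refo) - n_bare * p$mu), 3 * se_refo)
})

test_that("simulations are bit-reproducible for a fixed seed", {
  p <- yearly_params(g = 5, alpha = 0.2, mu = 0.5)
  a <- simulate_agents(p, n_parcels = 300, horizon = 80, seed = 9)
  b <- simulate_agents(p, n_parcels = 300, horizon = 80, seed = 9)
  c <- simulate_agents(p, n_parcels = 300, horizon = 80, seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("class densities stay consistent along a trajectory", {
  p <- reforest_params(g = 5, alpha = 0.9, mu = 0.5)
  tr <- simulate_agents(p, n_parcels = 400, horizon = 120, seed = 2)
  expect_true(all(tr$x >= 0 & tr$x <= 1))
  expect_true(all(tr$y >= 0 & tr$y <= 1 - tr$x + 1e-12))
  expect_true(all(tr$w <= tr$x + 1e-12)) # just-reforested parcels are forested
  expect_true(all(tr$r >= 0 & tr$r <= 1))
})

test_that("with no gain from deforesting the landscape fills with forest", {
  p <- forest_params(b = 20, c = 0, alpha = 0.2, mu = 0.3)
  tr <- simulate_agents(p, n_parcels = 2000, horizon = 150, seed = 4)
  expect_gt(mean(tr$x[101:150]), 0.99)
})

test_that("frozen-belief cover matches the exact three-state chain stationary law", {
  # brute-force oracle: stationary distribution of the chain on
  # {forested, just-deforested, bare} via the transition-matrix eigenvector
  r <- 0.15
  mu <- 0.25
  P <- rbind(
    forested = c(1 - r, r, 0),
    just_deforested = c(mu, 0, 1 - mu),
    bare = c(mu, 0, 1 - mu)
  )
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  x_oracle <- stat[1]
  expect_equal(x_oracle, mu / (mu + r), tolerance = 1e-12)

  p <- forest_params(b = 5, c = 20, alpha = 0, mu = mu)
  tr <- simulate_agents(p, n_parcels = 4000, horizon = 1200, seed = 5,
                        beliefs = beliefs_for_rate(r))
  x_bar <- mean(tr$x[401:1200])
  # Monte-Carlo tolerance: autocorrelated series, allow a generous band
  expect_lt(abs(x_bar - x_oracle), 0.02)
})

test_that("agent dynamics approach the mean-field dynamics as N grows", {
  p <- forest_params(b = 5, c = 20, g = 0, alpha = 0.05, mu = 0.1)
  mf <- simulate_meanfield(p, horizon = 150)
  rms <- vapply(c(100, 1000, 10000), function(N) {
    xbar <- rowMeans(vapply(1:20, function(s) {
      simulate_agents(p, n_parcels = N, horizon = 150, seed = s)$x
    }, numeric(150)))
    sqrt(mean((xbar - mf$x)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("long-run agent cover matches the mean-field attractor in a stable regime", {
  p <- forest_params(b = 5, c = 20, g = 10, alpha = 0.05, mu = 0.1,
                     governance = "yearly_incentive")
  mf_mean <- mean(simulate_meanfield(p, 600)$x[501:600])
  ag_mean <- mean(simulate_agents(p, n_parcels = 10000, horizon = 600,
                                  seed = 3)$x[501:600])
  expect_lt(abs(ag_mean - mf_mean), 0.01)
  expect_lt(abs(mf_mean - interior_equilibrium(p)$x_star), 1e-3)
})
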