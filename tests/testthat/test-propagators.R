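test_that("splitting probabilities and mean waiting times: closed forms", {
  expect_equal(splitting_probabilities(neighborhood_spec(c(1, 1, 1))),
               rep(1 / 3, 3))
  expect_equal(splitting_probabilities(neighborhood_spec(c(1, 2))),
               c(2 / 3, 1 / 3))
  expect_equal(mean_waiting_time(neighborhood_spec(1, D = 1)), 0.5)
  expect_equal(mean_waiting_time(neighborhood_spec(c(1, 2), D = 1)), 1.0)
})

test_that("degree-1 neighborhood reproduces the reflecting interval", {
  nb <- neighborhood_spec(1)
  s <- c(0.3, 1, 5, 50)
  expect_equal(node_flux_laplace(nb, 1, s), 1 / cosh(sqrt(s)),
               tolerance = 1e-12)
  # large-argument stability: finite (underflows gracefully to 0, never NaN)
  expect_true(is.finite(node_flux_laplace(nb, 1, 1e6)))
  expect_gte(node_flux_laplace(nb, 1, 1e6), 0)
  expect_gt(node_flux_laplace(nb, 1, 400), 0)
})

test_that("survival transform identity Q = (1 - sum P)/s for inert neighborhoods", {
  set.seed(1)
  for (rep in 1:5) {
    d <- sample(1:4, 1)
    nb <- neighborhood_spec(runif(d, 0.3, 2.5), D = runif(1, 0.5, 2))
    for (s in c(0.01, 0.7, 3)) {
      ps <- vapply(seq_len(d), function(k) node_flux_laplace(nb, k, s),
                   numeric(1))
      expect_rel_equal(node_survival_laplace(nb, s), (1 - sum(ps)) / s, 1e-10)
      expect_lte(sum(ps), 1)
    }
  }
})

test_that("reactive neighborhood: reaction probability and waiting time vs BD oracle", {
  nb <- neighborhood_spec(c(1, 1), gamma = c(10, 10), D = 1)
  ps <- splitting_probabilities(nb)
  expect_lt(sum(ps), 1)
  p_react <- 1 - sum(ps)
  expect_gt(p_react, 0)
  qq <- mean_waiting_time(nb)
  # BD with killing: chain 0-1-2, both edges gamma=10, absorbing ends, start center
  net <- chain_network(3, 1)
  tg <- target_set(nodes = c(0, 2),
                   edges = data.frame(edge = 1:2, gamma = 10))
  set.seed(5)
  bd <- bd_first_passage(net, list(node = 1), tg, D = 1, dt = 2e-5,
                         n_paths = 4000)
  sem <- sd(bd$time) / sqrt(nrow(bd))
  expect_lt(abs(mean(bd$time) - qq), 3 * sem + 2e-3) # small O(sqrt(dt)) bias slack
  p_hat <- mean(bd$outcome == "reacted")
  expect_lt(abs(p_hat - p_react), 4 * sqrt(p_hat * (1 - p_hat) / nrow(bd)) + 0.01)
})

test_that("edge propagators: uniform and point starts", {
  e <- edge_spec(1, D = 1)
  # s->0 limits: mean exit 1/12, split 1/2
  expect_equal(edge_survival_laplace(e, 0), 1 / 12)
  expect_equal(edge_flux_laplace(e, s = 0), 0.5)
  # symmetric point start: equal fluxes at all s
  ep <- edge_spec(1, D = 1, x0 = 0.5)
  for (s in c(0.1, 2, 40))
    expect_equal(edge_flux_laplace(ep, "near", s), edge_flux_laplace(ep, "far", s))
  # point-start survival limit x0 (l - x0) / (2D)
  ep2 <- edge_spec(2, D = 1, x0 = 0.6)
  expect_rel_equal(edge_survival_laplace(ep2, 0), 0.6 * 1.4 / 2, 1e-9)
})

test_that("transform derivatives at s = 0 match numerical differentiation", {
  nb1 <- neighborhood_spec(1)
  expect_equal(flux_derivative_s0(nb1, 1), -0.5)
  expect_equal(survival_derivative_s0(nb1), -5 / 24)
  set.seed(2)
  for (rep in 1:4) {
    d <- sample(1:3, 1)
    nb <- neighborhood_spec(runif(d, 0.4, 2), D = runif(1, 0.5, 2))
    h <- 1e-6
    rich <- function(f) { # Richardson-extrapolated forward difference, O(h^2)
      f0 <- f(0)
      2 * (f(h) - f0) / h - (f(2 * h) - f0) / (2 * h)
    }
    for (k in seq_len(d)) {
      numc <- rich(function(s) node_flux_laplace(nb, k, s))
      expect_rel_equal(flux_derivative_s0(nb, k), numc, 1e-6)
    }
    numq <- rich(function(s) node_survival_laplace(nb, s))
    expect_rel_equal(survival_derivative_s0(nb), numq, 1e-6)
  }
  # reactive complex-step derivative agrees with real finite differences
  nbr <- neighborhood_spec(c(1, 1.5), gamma = c(2, 0), D = 1)
  h <- 1e-5
  numd <- (node_survival_laplace(nbr, h) - node_survival_laplace(nbr, 0)) / h
  expect_rel_equal(tubenet:::survival_derivative_s0_reactive(nbr), numd, 1e-4)
  expect_error(flux_derivative_s0(nbr, 1), "inert")
})
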