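test_that("MFPT matrix pipeline: one-dimensional closed forms", {
  net <- chain_network(3, 1)
  # reflecting far end: (L^2 - x^2) / (2D) with L = 2, x = 0
  expect_equal(mfpt(net, target_set(nodes = 2), start_nodes(0)), 2.0)
  # start on the target
  expect_equal(mfpt(net, target_set(nodes = 2), start_nodes(2)), 0)
  # single edge, both endpoints absorbing, uniform start: l^2 / (12 D)
  net2 <- chain_network(2, 1)
  expect_equal(mfpt(net2, target_set(nodes = c(0, 1)), start_edges()), 1 / 12)
  # diverging MFPT signalled
  expect_error(mfpt(net, target_set(), start_nodes(0)), "diverge")
})

test_that("survival transform is a decreasing function of s with H(0) = MFPT", {
  net <- chain_network(3, 1)
  tg <- target_set(nodes = 2)
  st <- start_nodes(0)
  h <- vapply(c(0, 0.2, 1, 5), function(s)
    survival_transform(net, tg, st, s = s), numeric(1))
  expect_equal(h[1], mfpt(net, tg, st))
  expect_true(all(diff(h) < 0))
  # Laplace-transform consistency: H(s) = E[(1 - e^(-s tau))/s] checked by
  # quadrature of the simulated FPT sample
  set.seed(33)
  fx <- fpt_sample(net, list(node = 0), 2, n = 4000)
  hs <- mean((1 - exp(-0.5 * fx)) / 0.5)
  expect_lt(abs(hs - survival_transform(net, tg, st, s = 0.5)),
            4 * sd((1 - exp(-0.5 * fx)) / 0.5) / sqrt(4000))
})

test_that("MFPT is invariant under node relabeling and degree-2 insertion", {
  net <- triangle_network(c(1, 1.3, 2))
  tau <- mfpt(net, target_set(nodes = 1), start_nodes(0))
  # relabel node ids
  net2 <- net
  map <- c(10L, 40L, 20L)
  net2$nodes$id <- map[match(net2$nodes$id, 0:2)]
  net2$edges$from <- map[match(net2$edges$from, 0:2)]
  net2$edges$to <- map[match(net2$edges$to, 0:2)]
  attr(net2, "node_index") <- NULL
  expect_equal(mfpt(net2, target_set(nodes = 40), start_nodes(10)), tau)
  # insert a redundant degree-2 node in the middle of edge 3 (2 -> 0)
  net3 <- net
  net3$nodes <- rbind(net3$nodes, data.frame(id = 9L, x = 0.2, y = 0.2, z = 0))
  l3 <- net3$edges$length[3]
  net3$edges <- rbind(net3$edges[-3, ],
                      data.frame(id = c(7L, 8L), from = c(2L, 9L), to = c(9L, 0L),
                                 length = c(0.4 * l3, 0.6 * l3)))
  attr(net3, "node_index") <- NULL
  expect_rel_equal(mfpt(net3, target_set(nodes = 1), start_nodes(0)), tau, 1e-9)
})

test_that("adding a target node weakly decreases the MFPT", {
  set.seed(20)
  net <- honeycomb_patch(1, 5, 4.5)
  ids <- net$nodes$id
  t1 <- sample(ids, 1)
  tau1 <- mfpt(net, target_set(nodes = t1), start_edges())
  t2 <- sample(setdiff(ids, t1), 1)
  tau2 <- mfpt(net, target_set(nodes = c(t1, t2)), start_edges())
  expect_lte(tau2, tau1 + 1e-12)
})

test_that("variance pipeline agrees with the exact density and the BD oracle", {
  # two-node network: reflecting interval, <t^2> = 5/12, var = 1/6
  net2 <- chain_network(2, 1)
  v <- fpt_variance(net2, target_set(nodes = 1), start_nodes(0))
  expect_equal(v$second_moment, 5 / 12, tolerance = 1e-12)
  expect_equal(v$var, 1 / 6, tolerance = 1e-12)
  # quadrature of the exact residue-series density gives the same moments
  dec <- spectral_decomposition(neighborhood_spec(1), P = 4000)
  du2 <- dec$u^2
  m2_series <- sum(2 * dec$R[, 1] / du2^3)
  expect_rel_equal(m2_series, 5 / 12, 1e-6)
  # chain A-B-C vs BD oracle
  net <- chain_network(3, 1)
  va <- fpt_variance(net, target_set(nodes = 2), start_nodes(0))
  set.seed(8)
  bd <- bd_first_passage(net, list(node = 0), 2, dt = 2e-4, n_paths = 3000)
  sem <- sd(bd$time) / sqrt(nrow(bd))
  expect_lt(abs(mean(bd$time) - va$mean), 4 * sem + 0.02)
  sd_sem <- sd(bd$time) / sqrt(2 * nrow(bd))
  expect_lt(abs(sd(bd$time) - va$sd), 4 * sd_sem + 0.02)
  # nonnegative variance across random networks and targets
  set.seed(21)
  for (i in 1:15) {
    net <- random_network()
    tg <- sample(net$nodes$id, 2)
    vv <- fpt_variance(net, target_set(nodes = tg), start_edges())
    expect_gte(vv$var, -1e-10)
  }
})

test_that("edge-start MFPT decomposes between bounds of point-start values", {
  net <- triangle_network(c(1, 1.3, 2))
  tg <- target_set(nodes = 1)
  tau_e <- mfpt(net, tg, start_edges())
  node_taus <- c(mfpt(net, tg, start_nodes(0)), mfpt(net, tg, start_nodes(2)))
  internal <- max(net$edges$length^2 / 12)
  expect_lte(tau_e, max(node_taus) + internal)
  expect_gte(tau_e, 0)
})

test_that("finite reactivity: absorbing limit and the 1D two-region closed form", {
  net <- chain_network(3, 1)
  # gamma -> infinity around node 1 behaves like node 1 absorbing
  tg_inf <- target_set(edges = data.frame(edge = 1:2, gamma = 1e6))
  tau_g <- mfpt(net, tg_inf, start_nodes(0))
  # huge reactivity everywhere kills almost immediately after entering an edge;
  # compare against absorbing-node limit of the *first edge* only
  tg_abs <- target_set(nodes = 1)
  tau_a <- mfpt(net, tg_abs, start_nodes(0))
  expect_lt(tau_g, tau_a) # reaction can also occur inside the first edge
  # reflecting at 0, reactive region [0, ell] rate k, absorbing at L:
  # piecewise ODE oracle for the mean time to react or be absorbed
  ode_oracle <- function(k, ell, L, D = 1) {
    # region 1 (0<z<ell): D T1'' - k T1 = -1 ; T1'(0) = 0
    # region 2: D T2'' = -1 ; T2(L) = 0; match T, T' at ell
    mu <- sqrt(k / D)
    # T1 = A cosh(mu z) + 1/k ; T2 = -z^2/(2D) + B z + C
    # unknowns A, B, C from T1(ell)=T2(ell), T1'(ell)=T2'(ell), T2(L)=0
    M <- rbind(c(cosh(mu * ell), -ell, -1),
               c(mu * sinh(mu * ell), -1, 0),
               c(0, L, 1))
    rhs <- c(-1 / k - ell^2 / (2 * D), -ell / D, L^2 / (2 * D))
    sol <- solve(M, rhs)
    sol[1] * cosh(0) + 1 / k # T at z = 0
  }
  for (prm in list(c(2, 1, 5), c(0.5, 2, 6), c(10, 0.4, 3))) {
    k <- prm[1]; ell <- prm[2]; L <- prm[3]
    netr <- spatial_network(
      nodes = data.frame(id = 0:2, x = c(0, ell, L), y = 0),
      edges = data.frame(id = 1:2, from = 0:1, to = 1:2))
    tgr <- target_set(nodes = 2, edges = data.frame(edge = 1, gamma = k))
    expect_rel_equal(mfpt(netr, tgr, start_nodes(0)),
                     ode_oracle(k, ell, L), 1e-8)
  }
  # gamma = 0 everywhere with no targets diverges
  expect_error(mfpt(net, target_set(edges = data.frame(edge = 1:2, gamma = 0)),
                    start_nodes(0)), "diverge")
})

test_that("1D reactive-region scan has an interior optimum; gamma = 0 gives L^2/2D", {
  sc <- run_reactive_region_1d(k_reg_ell = 2, ell_grid = seq(0.5, 8, 0.5), L = 10)
  i <- which.min(sc$mfpt)
  expect_gt(i, 1)
  expect_lt(i, nrow(sc))
  netr <- spatial_network(
    nodes = data.frame(id = 0:2, x = c(0, 3, 10), y = 0),
    edges = data.frame(id = 1:2, from = 0:1, to = 1:2))
  tg0 <- target_set(nodes = 2, edges = data.frame(edge = 1, gamma = 0))
  expect_equal(mfpt(netr, tg0, start_nodes(0)), 50) # L^2/(2D)
})

test_that("maturation model recovers both limiting start distributions", {
  set.seed(30)
  hb <- honeycomb_band(0.8, 4, 8)
  tg <- select_reactive_edges(hb, 10, 6, gamma = 1)
  st <- start_nodes(innermost_nodes(hb))
  direct <- mfpt(hb, tg, st)
  lam_hi <- 1e6 / min(hb$edges$length)^2
  expect_rel_equal(suppressWarnings(mfpt_maturation(hb, tg, lam_hi, st)),
                   direct, 0.005)
  unif <- mfpt(hb, tg, start_edges())
  lam_lo <- 1e-6 / max(hb$edges$length)^2
  expect_rel_equal(mfpt_maturation(hb, tg, lam_lo, st), unif, 0.005)
})

test_that("tagMFPT: continuum chain limit, symmetry, lower bound", {
  net <- chain_network(101, 1)
  expect_rel_equal(tag_mfpt(net), 100^2 / 6, 0.02)
  star <- star_network(3)
  taus <- vapply(1:3, function(v)
    mfpt(star, target_set(nodes = v), start_edges()), numeric(1))
  expect_equal(max(taus) - min(taus), 0, tolerance = 1e-10)
  net2 <- triangle_network()
  tmin <- min(vapply(net2$nodes$id, function(v)
    mfpt(net2, target_set(nodes = v), start_edges()), numeric(1)))
  expect_gte(tag_mfpt(net2), tmin)
})

test_that("MFPT-versus-distance profile: monotone on a chain, sd > mean near target", {
  net <- chain_network(21, 1)
  prof <- run_mfpt_vs_distance(net, target = 0)
  ord <- order(prof$network_dist)
  expect_true(all(diff(prof$mean[ord]) >= -1e-10))
  # nodes adjacent to the target show sd exceeding the mean
  near <- prof[prof$network_dist > 0 & prof$network_dist <= 2, ]
  expect_true(all(near$sd > near$mean))
})
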