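test_that("single-particle simulation matches the analytic chain MFPT", {
  net <- chain_network(3, 1)
  set.seed(14)
  fx <- fpt_sample(net, list(node = 0), 2, n = 4000)
  sem <- sd(fx) / sqrt(length(fx))
  expect_lt(abs(mean(fx) - 2.0), 4 * sem)
  # R-level event loop is distributionally identical to the compiled path
  fr <- vapply(1:400, function(i)
    simulate_single(net, list(node = 0), targets = 2)$fpt, numeric(1))
  ks <- suppressWarnings(stats::ks.test(fr, fx))
  expect_gt(ks$p.value, 1e-3)
})

test_that("snapshot positions follow the free-diffusion law at short times", {
  net <- chain_network(2, 40)  # one long edge; start mid-edge, far from ends
  set.seed(15)
  tgrid <- seq(0, 1, 0.1)
  snaps <- lapply(1:150, function(i)
    simulate_single(net, list(edge = 1, x = 20), stop = "max_time",
                    max_time = 1.0001, snapshots = tgrid)$snapshots)
  m <- msd_from_snapshots(snaps)
  fit <- coef(lm(msd ~ 0 + lag, data = m[m$lag > 0, ]))
  expect_lt(abs(fit - 2), 0.1) # MSD = 2 D t within 5%
  expect_equal(m$msd[m$lag == 0], 0)
})

test_that("first-passage densities: peaked from afar, heavy-tailed near the target", {
  net <- honeycomb_patch(1, 8, 7)
  set.seed(16)
  tgt <- net$nodes$id[which.min(net$nodes$x^2 + net$nodes$y^2)]
  nd <- net_distance(net, tgt, net$nodes$id)
  far <- net$nodes$id[which.max(nd)]
  near <- net$nodes$id[nd > 0][which.min(nd[nd > 0])]
  tab <- tubenet:::engine_tables(net, 1, tgt)
  f_far <- fpt_sample(net, list(node = far), tgt, n = 3000, tables = tab)
  f_near <- fpt_sample(net, list(node = near), tgt, n = 3000, tables = tab)
  # near-start: mode at short times (monotone-decaying, heavy tail):
  # median far below the mean; far-start: much less skewed
  expect_lt(median(f_near) / mean(f_near), 0.5)
  expect_gt(median(f_far) / mean(f_far), 0.5)
})

test_that("protective domain construction follows the published rules", {
  net <- star_network(3)
  # single particle on a node of an empty network: full neighborhood
  d1 <- build_domains(net, data.frame(node = 0))
  expect_equal(d1[[1]]$type, "node-neighborhood")
  # two particles on one edge: shared pair segment
  d2 <- build_domains(net, data.frame(node = NA, edge = 1, x = c(0.3, 0.6)))
  expect_equal(d2[[1]]$type, "edge-segment")
  expect_equal(sort(d2[[1]]$occupants), c(1, 2))
  # particle on node with another mid-adjacent-edge: node segment, arm <= gap/2
  d3 <- build_domains(net, data.frame(node = c(0, NA), edge = c(NA, 1),
                                      x = c(NA, 0.5)))
  i_node <- which(vapply(d3, function(d) d$type, "") == "node-segment")
  expect_length(i_node, 1)
  expect_lte(d3[[i_node]]$arm, 0.25 + 1e-12)
})

test_that("pair propagation matches the BD pair oracle on an interval", {
  net <- chain_network(2, 1)
  tab <- tubenet:::engine_tables(net, 1)
  set.seed(17)
  n <- 3000
  starts <- cbind(0L, rep(0.3, n), 0L, rep(0.7, n))
  enc <- tubenet:::cpp_pair_encounter_batch(tab$net, tab$classes, 1, starts,
                                            Inf, 1e9)
  bd <- tubenet:::bd_pair_encounter_interval(1, dt = 1e-5, n_pairs = 1500,
                                             x1 = 0.3, x2 = 0.7)
  sem <- sqrt(sd(enc)^2 / n + sd(bd)^2 / 1500)
  expect_lt(abs(mean(enc) - mean(bd)), 4 * sem + 2e-3)
  # mirrored configuration has the same encounter-time distribution
  starts_m <- cbind(0L, rep(1 - 0.7, n), 0L, rep(1 - 0.3, n))
  enc_m <- tubenet:::cpp_pair_encounter_batch(tab$net, tab$classes, 1,
                                              starts_m, Inf, 1e9)
  ks <- suppressWarnings(stats::ks.test(enc, enc_m))
  expect_gt(ks$p.value, 1e-3)
})

test_that("pair encounter on a branched junction matches the BD pair oracle", {
  # frozen oracle: fine-step BD simulation of two particles on a symmetric
  # 3-star (unit arms, D = 1), p1 at (arm 1, x = 0.5), p2 at (arm 2, x = 0.5),
  # encounter = crossing on a shared arm with Brownian-bridge correction:
  # dt = 2e-6, n = 6000 pairs -> mean 0.6008 +- 0.0071
  star <- star_network(3)
  tab <- tubenet:::engine_tables(star, 1)
  set.seed(23)
  n <- 3000
  starts <- cbind(0L, rep(0.5, n), 1L, rep(0.5, n))
  enc <- tubenet:::cpp_pair_encounter_batch(tab$net, tab$classes, 1, starts,
                                            Inf, 1e9)
  tol <- 4 * sqrt((sd(enc) / sqrt(n))^2 + 0.0071^2)
  expect_lt(abs(mean(enc) - 0.6008), tol + 0.005)
})

test_that("multi-particle: event times nondecreasing; marginals unaffected before contact", {
  net <- honeycomb_patch(1, 8, 7)
  set.seed(18)
  parts <- data.frame(node = sample(net$nodes$id, 3))
  res <- simulate_multi(net, parts, rule = "targets",
                        targets = net$nodes$id[1], tmax = 50)
  expect_true(all(diff(res$event_times) >= 0))
  expect_gt(length(res$event_times), 3)
  # two particles started far apart, absorbing target near one of them:
  # the tracked particle's absorption-time distribution matches a
  # single-particle run
  net2 <- chain_network(41, 1)
  tgt <- 40
  set.seed(19)
  t_multi <- vapply(1:250, function(i) {
    r <- simulate_multi(net2, data.frame(node = c(30, 0)), rule = "targets",
                        targets = tgt, tmax = 1e5)
    r$absorption_time[1]
  }, numeric(1))
  t_single <- fpt_sample(net2, list(node = 30), tgt, n = 3000)
  ks <- suppressWarnings(stats::ks.test(t_multi, t_single))
  expect_gt(ks$p.value, 1e-3)
})

test_that("seed determinism: identical seeds give identical simulations", {
  net <- honeycomb_patch(1, 6, 5)
  set.seed(77)
  e1 <- simulate_pair_encounters(net, 20)
  set.seed(77)
  e2 <- simulate_pair_encounters(net, 20)
  expect_identical(e1, e2)
  set.seed(78)
  e3 <- simulate_pair_encounters(net, 20)
  expect_false(identical(e1, e3))
})

test_that("extreme first-passage: N = 1 reduces to the single-particle mean", {
  net <- chain_network(11, 1)
  set.seed(22)
  ex <- extreme_first_passage(net, start = 0, target = 10, N_list = c(1, 4),
                              reps = 300)
  tau <- mfpt(net, target_set(nodes = 10), start_nodes(0))
  expect_lt(abs(ex$mean_min_fpt[1] - tau), 4 * ex$sem[1])
  expect_lt(ex$mean_min_fpt[2], ex$mean_min_fpt[1])
})
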