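test_that("honeycomb band matches the ER-like geometry", {
  net <- honeycomb_band(0.8, 8, 20)
  expect_true(all(abs(net$edges$length - 0.8) < 1e-12))
  deg <- tubenet:::node_index(net)$deg
  expect_lte(max(deg), 3)
  # areal node density 4/(3 sqrt(3) a^2) over the annulus
  expected_n <- 4 / (3 * sqrt(3) * 0.8^2) * pi * (20^2 - 8^2)
  expect_lt(abs(nrow(net$nodes) - expected_n) / expected_n, 0.15)
  # connected
  expect_true(igraph::is_connected(tubenet:::as_igraph(net)))
  r <- sqrt(net$nodes$x^2 + net$nodes$y^2)
  expect_true(all(r >= 8 - 1e-9 & r <= 20 + 1e-9))
  inn <- innermost_nodes(net)
  expect_gt(length(inn), 10)
  expect_true(all(sqrt(net$nodes$x[match(inn, net$nodes$id)]^2 +
                         net$nodes$y[match(inn, net$nodes$id)]^2) <= 8.8))
  expect_error(honeycomb_band(1, 1, 1.5), "")
})

test_that("chain generator produces a path graph", {
  net <- chain_network(3, 1)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$edges$length), 2)
  net2 <- chain_network(2, 0.5)
  expect_equal(net2$edges$length, 0.5)
  deg <- tubenet:::node_index(chain_network(6, 1))$deg
  expect_equal(sort(unique(deg)), c(1, 2))
  expect_equal(sum(deg == 1), 2)
  expect_error(chain_network(1), "at least 2")
})

test_that("decimation removes edges but never disconnects", {
  net <- honeycomb_patch(1, 8, 7)
  expect_identical(net_decimate(net, 0), net)
  # tree input: any removal disconnects
  tree <- chain_network(5, 1)
  expect_error(net_decimate(tree, 1), "cyclomatic")
  set.seed(2)
  n_rm <- nrow(net$edges) - (nrow(net$nodes) - 1L)
  dec <- net_decimate(net, n_rm)
  expect_equal(nrow(dec$edges), nrow(dec$nodes) - 1L) # spanning tree
  expect_true(igraph::is_connected(tubenet:::as_igraph(dec)))
  expect_true(all(dec$edges$id %in% net$edges$id)) # subset of input edges
  set.seed(9)
  d1 <- net_decimate(net, 10)
  set.seed(9)
  d2 <- net_decimate(net, 10)
  expect_identical(d1$edges$id, d2$edges$id) # deterministic under seed
})

test_that("reactive edge placement is uniform over the eligible set", {
  net <- honeycomb_band(0.8, 4, 8)
  mid <- tubenet:::edge_midpoints(net)
  r <- sqrt(mid[, 1]^2 + mid[, 2]^2)
  # no constraint binds
  set.seed(1)
  ts1 <- select_reactive_edges(net, 5, Inf, gamma = 2)
  expect_true(all(ts1$edges$edge %in% net$edges$id))
  expect_true(all(ts1$edges$gamma == 2))
  # n equals eligible count: deterministic (ties in radius are fine because
  # the whole eligible set is taken)
  n_el <- sum(r <= 6)
  ts2 <- select_reactive_edges(net, n_el, 6, gamma = 1)
  expect_setequal(ts2$edges$edge, net$edges$id[r <= 6])
  expect_error(select_reactive_edges(net, 1e4, 5), "eligible|within")
  # empirical placement frequency approximately n/|eligible|
  elig <- net$edges$id[r <= 6]
  counts <- setNames(numeric(length(elig)), elig)
  reps <- 2000
  set.seed(7)
  for (i in seq_len(reps)) {
    tg <- select_reactive_edges(net, 8, 6)
    counts[as.character(tg$edges$edge)] <-
      counts[as.character(tg$edges$edge)] + 1
  }
  p <- 8 / length(elig)
  sdev <- sqrt(reps * p * (1 - p))
  expect_true(all(abs(counts - reps * p) < 5 * sdev))
})
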