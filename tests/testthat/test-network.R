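test_that("text format round trip preserves positions and lengths", {
  net <- triangle_network(c(1, 1.2, 2.5))
  net$nodes$x <- net$nodes$x + pi * 1e-3 # non-trivial digits
  f <- tempfile(fileext = ".txt")
  net_write(net, f)
  net2 <- net_read(f)
  expect_equal(net2$nodes$x, net$nodes$x, tolerance = 1e-12)
  expect_equal(net2$nodes$y, net$nodes$y, tolerance = 1e-12)
  expect_equal(net2$edges$length, net$edges$length, tolerance = 1e-12)
  expect_equal(net2$edges$from, net$edges$from)
})

test_that("missing lengths default to Euclidean distance; curved edges allowed", {
  f <- tempfile()
  writeLines(c("# two nodes one edge", "NODE 0 0 0", "NODE 1 1 0",
               "EDGE 1 0 1"), f)
  net <- net_read(f)
  expect_equal(net$edges$length, 1.0)
  writeLines(c("NODE 0 0 0", "NODE 1 1 0", "EDGE 1 0 1 2.5"), f)
  expect_equal(net_read(f)$edges$length, 2.5) # curved: longer than Euclidean
  writeLines(c("NODE 0 0 0", "NODE 1 1 0", "EDGE 1 0 1 0.5"), f)
  expect_error(net_read(f), "shorter than the Euclidean")
})

test_that("referential integrity errors name the offending id", {
  f <- tempfile()
  writeLines(c("NODE 0 0 0", "NODE 1 1 0", "EDGE 1 0 7"), f)
  expect_error(net_read(f), "7")
  expect_error(spatial_network(data.frame(id = 0, x = 0, y = 0),
                               data.frame(id = 1, from = 0, to = 0,
                                          length = -1)),
               "length")
})

test_that("normalization removes self-loops and parallel edges, conserving length", {
  # two parallel edges between A and B
  net <- spatial_network(
    nodes = data.frame(id = 0:1, x = c(0, 1), y = 0),
    edges = data.frame(id = 1:2, from = 0, to = 1, length = c(1, 1.4)),
    validate = FALSE)
  nn <- net_normalize(net)
  key <- paste(pmin(nn$edges$from, nn$edges$to), pmax(nn$edges$from, nn$edges$to))
  expect_false(any(duplicated(key)))
  expect_equal(sum(nn$edges$length), 2.4)
  # self-loop of length 3
  net2 <- spatial_network(
    nodes = data.frame(id = 0:1, x = c(0, 1), y = 0),
    edges = data.frame(id = 1:2, from = c(0, 0), to = c(1, 0),
                       length = c(1, 3)), validate = FALSE)
  nn2 <- net_normalize(net2)
  expect_equal(sum(nn2$edges$length), 4)
  expect_false(any(nn2$edges$from == nn2$edges$to))
  # simple network unchanged; idempotent
  tri <- triangle_network()
  expect_identical(net_normalize(tri), tri)
  expect_equal(net_normalize(nn2)$edges, nn2$edges)
})

test_that("network distance: shortest path along edges", {
  tri <- triangle_network(c(1, 1, 3)) # long curved third edge
  expect_equal(net_distance(tri, 0, 2), 2) # two short edges beat the long one
  expect_equal(net_distance(tri, 0, 0), 0)
  expect_equal(net_distance(tri, 0, 1), net_distance(tri, 1, 0))
  # triangle inequality over sampled triples on a bigger network
  net <- honeycomb_patch(1, 6, 5)
  ids <- net$nodes$id
  set.seed(4)
  for (i in 1:25) {
    abc <- sample(ids, 3)
    dab <- net_distance(net, abc[1], abc[2])
    dbc <- net_distance(net, abc[2], abc[3])
    dac <- net_distance(net, abc[1], abc[3])
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("disconnected node pairs are reported", {
  net <- spatial_network(
    nodes = data.frame(id = 0:3, x = c(0, 1, 5, 6), y = 0),
    edges = data.frame(id = 1:2, from = c(0, 2), to = c(1, 3)))
  expect_error(net_distance(net, 0, 3), "components")
})
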