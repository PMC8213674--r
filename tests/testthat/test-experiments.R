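test_that("search-rate experiment: consistency and the all-target plateau", {
  net <- honeycomb_patch(1, 6, 5)
  set.seed(40)
  # single fixed count, one placement: agrees with a direct mfpt call
  set.seed(41)
  tab <- run_search_rate_vs_density(net, target_counts = 3, realizations = 5)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$rate, 0)
  expect_equal(tab$rate, 1 / tab$mfpt)
  # dense limit: every node a target -> finite plateau (within-edge capture)
  all_tau <- mfpt(net, target_set(nodes = net$nodes$id), start_edges())
  expect_true(is.finite(all_tau))
  expect_equal(all_tau, mean(net$edges$length^2) / 12, tolerance = 1e-10)
  # rates increase with target count
  set.seed(42)
  tab2 <- run_search_rate_vs_density(net, target_counts = c(2, 8),
                                     realizations = 20)
  expect_gt(tab2$rate[2], tab2$rate[1])
})

test_that("pair-encounter experiment table is reproducible from the seed", {
  net <- chain_network(21, 1)
  set.seed(43)
  r1 <- run_pair_encounter(list(chain = net), n_pairs = 40)
  set.seed(43)
  r2 <- run_pair_encounter(list(chain = net), n_pairs = 40)
  expect_identical(r1, r2)
  expect_true(is.finite(r1$ratio))
  expect_gt(r1$ratio, 0.2)
  expect_lt(r1$ratio, 0.7)
  expect_equal(r1$tag_mfpt, tag_mfpt(net))
})

test_that("honeycomb scan table carries SEMs and respects eligibility", {
  hb <- honeycomb_band(0.8, 4, 8)
  set.seed(44)
  sc <- run_honeycomb_target_scan(hb, max_dist_grid = c(3, 5, 7, 8),
                                  n_edges = 8, gamma = 1,
                                  realizations = 10)
  expect_true(all(sc$n_eligible >= 8))
  expect_false(3 %in% sc$max_dist) # infeasible point skipped
  expect_true(all(sc$sem >= 0))
})
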