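test_that("pole locations: closed-form cases and bracketing", {
  nb1 <- neighborhood_spec(1)
  u <- find_poles(nb1, 8)
  expect_equal(u, (seq_len(8) - 0.5) * pi, tolerance = 1e-10)
  # equal-length degree 3: same reduction d * cos(l u) = 0
  nb3 <- neighborhood_spec(rep(0.7, 3))
  u3 <- find_poles(nb3, 6)
  expect_equal(u3, (seq_len(6) - 0.5) * pi / 0.7, tolerance = 1e-10)
  # incommensurate lengths: every root strictly between adjacent distinct
  # singularities, validated by sign change of sum(cot)
  nb <- neighborhood_spec(c(1, 2))
  u2 <- find_poles(nb, 12)
  expect_true(all(diff(u2) > 0))
  Ffun <- function(x) sum(1 / tan(c(1, 2) * x))
  for (r in u2) {
    expect_lt(abs(Ffun(r)), 1e-6)
    sing <- sort(c(pi * (1:12), pi * (1:24) / 2))
    expect_gt(min(abs(r - sing)), 1e-6) # never on a singularity
  }
})

test_that("residues reproduce the classical interval series and normalization", {
  nb1 <- neighborhood_spec(1, D = 1)
  u <- find_poles(nb1, 50)
  r <- residues(nb1, 1, u)
  # classical: D (2p-1) pi (-1)^(p-1)
  p <- seq_along(u)
  expect_equal(r, (2 * p - 1) * pi * (-1)^(p - 1), tolerance = 1e-9)
  dec <- spectral_decomposition(nb1)
  expect_rel_equal(residue_normalization(dec), 1, 1e-6)
  # general neighborhood: sum_p r / (D u^2) = splitting probability;
  # second identity: first moment sums to the mean waiting time
  nb <- neighborhood_spec(c(0.6, 1.1, 1.7), D = 1.3)
  dec2 <- spectral_decomposition(nb)
  Ps <- splitting_probabilities(nb)
  du2 <- nb$D * dec2$u^2
  rn <- residue_normalization(dec2)
  for (k in 1:3)
    expect_rel_equal(rn[k], Ps[k], 1e-6)
  m1 <- sum(colSums(dec2$R / du2^2))
  expect_rel_equal(m1, mean_waiting_time(nb), 1e-6)
  # symmetric degree 3: identical residues across edges
  dec3 <- spectral_decomposition(neighborhood_spec(rep(1, 3)), P = 20)
  expect_equal(dec3$R[, 1], dec3$R[, 2])
  expect_equal(dec3$R[, 1], dec3$R[, 3])
})

test_that("transition density matches independent Talbot inversion", {
  dec <- spectral_decomposition(neighborhood_spec(1), P = 200)
  for (t in c(0.05, 0.3, 1)) {
    direct <- transition_density(dec, 1, t)
    talbot <- talbot_invert(function(s) 1 / cosh(sqrt(s)), t)
    expect_rel_equal(direct, talbot, 1e-8)
  }
})

test_that("exit sampler reproduces splitting probabilities, mean, and CDF", {
  set.seed(10)
  nb <- neighborhood_spec(c(0.8, 1.3, 2.1))
  dec <- spectral_decomposition(nb)
  n <- 2e4
  s <- sample_exit(dec, n)
  Ps <- splitting_probabilities(nb)
  for (k in 1:3) {
    phat <- mean(s$edge == k)
    expect_lt(abs(phat - Ps[k]), 4 * sqrt(Ps[k] * (1 - Ps[k]) / n))
  }
  qq <- mean_waiting_time(nb)
  expect_lt(abs(mean(s$dt) - qq), 4 * sd(s$dt) / sqrt(n))
  # K-S against the exact conditional CDF for one exit edge
  du2 <- nb$D * dec$u^2
  cdf1 <- function(t) {
    vapply(t, function(tt)
      1 - sum(dec$R[, 1] / du2 * exp(-du2 * tt)) / Ps[1], numeric(1))
  }
  d1 <- s$dt[s$edge == 1]
  ks <- suppressWarnings(stats::ks.test(d1, cdf1))
  expect_gt(ks$p.value, 1e-3)
})

test_that("no-passage distribution: survival consistency and image-series check", {
  nb <- neighborhood_spec(c(1, 1.6))
  dec <- spectral_decomposition(nb)
  du2 <- dec$u^2
  for (t in c(0.05, 0.4)) {
    y <- sum(vapply(1:2, function(k) no_passage_cdf(dec, k, 0, t), numeric(1)))
    surv <- sum(vapply(1:2, function(k)
      sum(dec$R[, k] / du2 * exp(-du2 * t)), numeric(1)))
    expect_rel_equal(y, surv, 1e-9)
  }
  # d = 1: no-passage spatial density equals the image-series Green function
  dec1 <- spectral_decomposition(neighborhood_spec(1))
  t <- 0.08
  set.seed(3)
  smp <- sample_no_passage(dec1, t, 1e4)
  # image CDF of distance-from-start r (start at reflecting end = center node)
  img_cdf <- function(r) {
    num <- function(x) {
      s <- 0
      for (n in -4:4) s <- s + (-1)^n * stats::dnorm(x - 2 * n, 0, sqrt(2 * t))
      s
    }
    den <- stats::integrate(Vectorize(num), 0, 1)$value
    vapply(r, function(rr)
      stats::integrate(Vectorize(num), 0, rr)$value / den, numeric(1))
  }
  ks <- suppressWarnings(stats::ks.test(smp$r, img_cdf))
  expect_gt(ks$p.value, 1e-3)
  # short-lag displacement collapses onto the diffusive scale
  dt_small <- 1e-6
  smp2 <- sample_no_passage(dec1, dt_small, 2000)
  expect_lt(stats::median(smp2$r), 3 * sqrt(dt_small))
})

test_that("interval sampler: splitting, mean exit, uniform-start mean", {
  set.seed(11)
  s <- interval_sample_exit(1, 0.5, 1, 5000)
  expect_lt(abs(mean(s$side) - 0.5), 4 * sqrt(0.25 / 5000))
  x0 <- 0.3; l <- 1.4
  s2 <- interval_sample_exit(l, x0, 1, 2e4)
  mexp <- x0 * (l - x0) / 2
  expect_lt(abs(mean(s2$dt) - mexp), 4 * sd(s2$dt) / sqrt(2e4))
  expect_lt(abs(mean(s2$side == 1) - x0 / l), 4 * sqrt(x0 / l * (1 - x0 / l) / 2e4))
  # uniform start (fresh x0 per draw): mean l^2 / 12
  dts <- vapply(1:2500, function(i)
    interval_sample_exit(l, runif(1) * l, 1, 1)$dt, numeric(1))
  expect_lt(abs(mean(dts) - l^2 / 12), 5 * sd(dts) / sqrt(length(dts)))
})

test_that("no-passage then exit composes to the unconditional exit law", {
  # Chapman-Kolmogorov: propagating to t0 with the no-passage propagator and
  # then drawing a fresh exit reproduces the direct exit-time distribution
  set.seed(12)
  l <- 1; x0 <- 0.35; t0 <- 0.03
  n <- 8000
  direct <- interval_sample_exit(l, x0, 1, n)$dt
  surv_split <- numeric(n); comp <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- interval_sample_exit(l, x0, 1, 1)
    if (d1$dt <= t0) comp[i] <- d1$dt
    else {
      xm <- interval_sample_position(l, x0, 1, t0, 1)$x
      comp[i] <- t0 + interval_sample_exit(l, xm, 1, 1)$dt
    }
  }
  ks <- suppressWarnings(stats::ks.test(direct, comp))
  expect_gt(ks$p.value, 1e-3)
})
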