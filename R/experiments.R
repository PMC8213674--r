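# Scripted experiments on synthetic geometries: each returns a tidy
# data.frame with SEMs wherever averaging over random placements or
# particles occurs, and is reproducible from the caller's RNG seed.

#' Search rate versus target density
#'
#' For each target count, distributes that many absorbing target nodes
#' uniformly at random over the network, computes the MFPT from an
#' edge-uniform start, and reports the search rate (inverse of the
#' placement-averaged MFPT) against the target concentration per tube
#' length. On well-connected planar networks the rate scales as
#' \eqn{\rho/\log\rho} at low density, crossing over to one-dimensional
#' \eqn{\rho^2} scaling once the typical target spacing falls below the
#' edge length.
#'
#' @param net a `spatial_network`.
#' @param target_counts vector of numbers of target nodes.
#' @param realizations random placements per count.
#' @param D diffusivity.
#' @return data.frame with `n_targets`, `rho` (targets per \eqn{\mu m} of
#'   tube), `mfpt`, `sem`, `rate`.
#' @export
run_search_rate_vs_density <- function(net, target_counts, realizations = 50,
                                       D = 1) {
  L <- sum(net$edges$length)
  out <- lapply(target_counts, function(nt) {
    taus <- vapply(seq_len(realizations), function(r) {
      tg <- sample(net$nodes$id, nt)
      mfpt(net, target_set(nodes = tg), start_edges(), D = D)
    }, numeric(1))
    data.frame(n_targets = nt, rho = nt / L, mfpt = mean(taus),
               sem = stats::sd(taus) / sqrt(realizations),
               rate = 1 / mean(taus))
  })
  do.call(rbind, out)
}

#' Reactive region on a one-dimensional domain
#'
#' A tube of length `L` with a reflecting end at z = 0 (where particles are
#' produced), a perfectly absorbing end at z = L, and a partially reactive
#' region on \eqn{[0, \ell]} with rate \eqn{k_{reg} = n k_a \xi / \ell}
#' (total reactivity \eqn{k_{reg}\ell} held fixed while the region length
#' \eqn{\ell} varies). Reports the mean time for a particle starting at
#' z = 0 to either react in the region or reach the absorbing end. An
#' interior optimum of \eqn{\ell} exists at moderate total reactivity.
#'
#' @param k_reg_ell total reactivity \eqn{k_{reg}\,\ell} (\eqn{\mu m}/s).
#' @param ell_grid region lengths to scan (0 < ell < L).
#' @param L domain length.
#' @param D diffusivity.
#' @return data.frame with `ell`, `k_reg`, `mfpt`.
#' @export
run_reactive_region_1d <- function(k_reg_ell, ell_grid, L = 10, D = 1) {
  out <- lapply(ell_grid, function(ell) {
    stopifnot(ell > 0, ell < L)
    net <- spatial_network(
      nodes = data.frame(id = 0:2, x = c(0, ell, L), y = 0),
      edges = data.frame(id = 1:2, from = 0:1, to = 1:2))
    k_reg <- k_reg_ell / ell
    tg <- target_set(nodes = 2, edges = data.frame(edge = 1, gamma = k_reg))
    data.frame(ell = ell, k_reg = k_reg,
               mfpt = mfpt(net, tg, start_nodes(0), D = D))
  })
  do.call(rbind, out)
}

#' Reactive-edge placement scan on the honeycomb band
#'
#' Places `n_edges` reactive edges (rate `gamma`) uniformly among edges
#' whose midpoint radius is at most each value of `max_dist_grid`, computes
#' the MFPT for particles starting uniformly on the innermost nodes
#' (optionally with a finite maturation rate `lambda`), and averages over
#' `realizations` random placements. Placements are coupled across grid
#' points (common random numbers per realization index) to reduce the
#' variance of comparisons along the scan. Grid points with fewer than
#' `n_edges` eligible edges are skipped.
#'
#' @param net a [honeycomb_band()] network (or compatible, with `center`
#'   attribute).
#' @param max_dist_grid maximum radial distances to scan (\eqn{\mu m}).
#' @param n_edges number of reactive edges per placement.
#' @param gamma reaction rate (1/s).
#' @param lambda maturation rate (1/s); `Inf` for no maturation.
#' @param realizations placements per grid point.
#' @param D diffusivity.
#' @return data.frame with `max_dist`, `lambda`, `gamma`, `mfpt`, `sem`,
#'   `n_eligible`.
#' @export
run_honeycomb_target_scan <- function(net, max_dist_grid = 9:20, n_edges = 30,
                                      gamma = 1, lambda = Inf,
                                      realizations = 100, D = 1) {
  start <- start_nodes(innermost_nodes(net))
  mid <- edge_midpoints(net)
  r_mid <- sqrt(mid[, 1]^2 + mid[, 2]^2)
  seeds <- sample.int(.Machine$integer.max, realizations)
  out <- list()
  for (md in max_dist_grid) {
    n_elig <- sum(r_mid <= md)
    if (n_elig < n_edges) next
    taus <- vapply(seq_len(realizations), function(r) {
      set.seed(seeds[r])
      tg <- select_reactive_edges(net, n_edges, md, gamma)
      if (is.finite(lambda)) mfpt_maturation(net, tg, lambda, start, D = D)
      else mfpt(net, tg, start, D = D)
    }, numeric(1))
    out[[length(out) + 1]] <-
      data.frame(max_dist = md, lambda = lambda, gamma = gamma,
                 mfpt = mean(taus), sem = stats::sd(taus) / sqrt(realizations),
                 n_eligible = n_elig)
  }
  do.call(rbind, out)
}

#' Pair encounter time relative to the stationary-target search time
#'
#' Simulates independent pairs of diffusing particles (uniform edge starts)
#' to estimate the mean encounter time, computes the target-averaged global
#' MFPT ([tag_mfpt()]) analytically, and reports their ratio. On an
#' interval the ratio is about 0.42; on poorly connected (near-tree)
#' networks it drops to about 0.3.
#'
#' @param nets named list of `spatial_network` objects.
#' @param n_pairs simulated pairs per network.
#' @param D diffusivity.
#' @param tmax censoring horizon for the pair simulation (default: none).
#' @return data.frame with `network`, `tau_enc`, `tau_enc_sem`, `tag_mfpt`,
#'   `ratio`, `ratio_sem`.
#' @export
run_pair_encounter <- function(nets, n_pairs = 500, D = 1, tmax = Inf) {
  if (inherits(nets, "spatial_network")) nets <- list(network = nets)
  out <- lapply(names(nets), function(nm) {
    net <- nets[[nm]]
    enc <- simulate_pair_encounters(net, n_pairs, D = D, tmax = tmax)
    enc <- enc[!is.na(enc)]
    tm <- tag_mfpt(net, D = D)
    data.frame(network = nm, tau_enc = mean(enc),
               tau_enc_sem = stats::sd(enc) / sqrt(length(enc)),
               tag_mfpt = tm, ratio = mean(enc) / tm,
               ratio_sem = stats::sd(enc) / sqrt(length(enc)) / tm)
  })
  do.call(rbind, out)
}

#' MFPT and its standard deviation versus distance from a target
#'
#' Single fixed target; per-node mean and standard deviation of the
#' first-passage time together with the Euclidean and network distance of
#' each start node from the target. Near the target the standard deviation
#' substantially exceeds the mean (a signature of compact, geometry
#' controlled search).
#'
#' @param net a `spatial_network`.
#' @param target target node id.
#' @param D diffusivity.
#' @return data.frame with `node`, `euclid_dist`, `network_dist`, `mean`,
#'   `sd`.
#' @export
run_mfpt_vs_distance <- function(net, target, D = 1) {
  prof <- mfpt_profile(net, target_set(nodes = target), D = D)
  ti <- match(target, net$nodes$id)
  eu <- sqrt((net$nodes$x - net$nodes$x[ti])^2 +
               (net$nodes$y - net$nodes$y[ti])^2)
  nd <- net_distance(net, target, net$nodes$id)
  data.frame(node = prof$node, euclid_dist = eu, network_dist = nd,
             mean = prof$mean, sd = prof$sd)
}
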