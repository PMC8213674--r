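#' Honeycomb lattice in a circular band
#'
#' Generates a hexagonal (honeycomb) lattice with uniform edge length,
#' clipped to the annulus between `r_inner` and `r_outer` around the origin.
#' Only the largest connected component is kept; interior nodes have degree
#' 3. The default dimensions emulate a peripheral-ER-like geometry: edge
#' length 0.8 um, inner radius 8 um (nuclear boundary), outer radius
#' 20 um (cell boundary).
#'
#' The "innermost" nodes (those within one edge length of the inner radius),
#' typically used as the start distribution for particles synthesized at the
#' perinuclear boundary, are available via [innermost_nodes()].
#'
#' @param edge_len edge length \eqn{a} (\eqn{\mu m}).
#' @param r_inner,r_outer annulus radii (\eqn{\mu m}), `0 < r_inner < r_outer`.
#' @return a `spatial_network` with attributes `edge_len`, `r_inner`,
#'   `r_outer`, `center`.
#' @export
#' @examples
#' net <- honeycomb_band(0.8, 8, 20)
#' length(innermost_nodes(net))
honeycomb_band <- function(edge_len = 0.8, r_inner = 8, r_outer = 20) {
  stopifnot(r_inner > 0, r_outer > r_inner, edge_len > 0,
            edge_len < (r_outer - r_inner))
  net <- honeycomb_clip(edge_len,
                        function(x, y) {
                          r <- sqrt(x^2 + y^2)
                          r >= r_inner & r <= r_outer
                        },
                        reach = r_outer)
  attr(net, "edge_len") <- edge_len
  attr(net, "r_inner") <- r_inner
  attr(net, "r_outer") <- r_outer
  attr(net, "center") <- c(0, 0)
  net
}

#' Rectangular honeycomb lattice patch
#'
#' A planar lattice-like network with degree-3 interior nodes, used for
#' lattice/decimation experiments.
#'
#' @param edge_len edge length (\eqn{\mu m}).
#' @param width,height dimensions of the rectangular clip window.
#' @return a `spatial_network`.
#' @export
honeycomb_patch <- function(edge_len = 1, width = 16, height = 14) {
  stopifnot(edge_len > 0, width > 0, height > 0)
  net <- honeycomb_clip(edge_len,
                        function(x, y) abs(x) <= width / 2 & abs(y) <= height / 2,
                        reach = sqrt(width^2 + height^2) / 2)
  attr(net, "edge_len") <- edge_len
  attr(net, "center") <- c(0, 0)
  net
}

# shared honeycomb machinery: two triangular sublattices
#   A(i,j) = (sqrt(3) a (i + j/2), 1.5 a j),  B(i,j) = A(i,j) + (0, a)
# B(i,j) connects to A(i,j), A(i,j+1), A(i-1,j+1); every edge has length a.
honeycomb_clip <- function(a, keep_fun, reach) {
  m <- ceiling(reach / a) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  ax <- sqrt(3) * a * (ij$i + ij$j / 2); ay <- 1.5 * a * ij$j
  bx <- ax; by <- ay + a
  key <- function(i, j, sub) paste(i, j, sub)
  ids <- c(key(ij$i, ij$j, "A"), key(ij$i, ij$j, "B"))
  px <- c(ax, bx); py <- c(ay, by)
  keep <- keep_fun(px, py)
  if (!any(keep)) stop("clip region contains no lattice nodes")
  id_map <- seq_len(sum(keep)) - 1L
  names(id_map) <- ids[keep]
  # candidate edges from each B node
  nb <- rbind(cbind(ij$i, ij$j), cbind(ij$i, ij$j + 1L), cbind(ij$i - 1L, ij$j + 1L))
  bfrom <- rep(key(ij$i, ij$j, "B"), 3)
  bto <- key(nb[, 1], nb[, 2], "A")
  ok <- bfrom %in% names(id_map) & bto %in% names(id_map)
  if (!any(ok)) stop("clip region contains no lattice edges")
  edges <- data.frame(id = seq_len(sum(ok)),
                      from = unname(id_map[bfrom[ok]]),
                      to = unname(id_map[bto[ok]]),
                      length = a)
  nodes <- data.frame(id = id_map, x = px[keep], y = py[keep])
  net <- spatial_network(nodes, edges, validate = FALSE)
  net <- largest_component(net)
  net_validate(net)
  net
}

#' Innermost nodes of a honeycomb band
#'
#' Nodes whose radius is at most `r_inner + edge_len` (within one edge length
#' of the inner boundary).
#'
#' @param net a network from [honeycomb_band()].
#' @return vector of node ids.
#' @export
innermost_nodes <- function(net) {
  ri <- attr(net, "r_inner"); a <- attr(net, "edge_len")
  if (is.null(ri) || is.null(a)) stop("not a honeycomb band network")
  r <- sqrt(net$nodes$x^2 + net$nodes$y^2)
  net$nodes$id[r <= ri + a]
}

#' Chain (path) network
#'
#' A single line of `n_nodes` collinear nodes connected by `n_nodes - 1`
#' equal edges. End nodes have degree 1 (effective reflecting ends);
#' interior nodes have degree 2.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edge_len edge length (\eqn{\mu m}).
#' @return a `spatial_network`.
#' @export
chain_network <- function(n_nodes, edge_len = 1) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  nodes <- data.frame(id = seq_len(n_nodes) - 1L,
                      x = (seq_len(n_nodes) - 1) * edge_len, y = 0)
  edges <- data.frame(id = seq_len(n_nodes - 1),
                      from = seq_len(n_nodes - 1) - 1L,
                      to = seq_len(n_nodes - 1),
                      length = edge_len)
  spatial_network(nodes, edges)
}

#' Randomly remove edges while preserving connectivity
#'
#' Removes `n_remove` randomly chosen edges, rejecting any removal that would
#' disconnect the network (a single connected cluster is maintained
#' throughout, so no isolated nodes can arise). Deterministic under a fixed
#' RNG seed.
#'
#' @param net a connected `spatial_network`.
#' @param n_remove number of edges to remove. The maximum removable number is
#'   `n_edges - (n_nodes - 1)` (down to a spanning tree).
#' @return the decimated `spatial_network`.
#' @export
net_decimate <- function(net, n_remove) {
  if (n_remove == 0) return(net)
  n_cyc <- nrow(net$edges) - (nrow(net$nodes) - 1L)
  if (n_remove > n_cyc)
    stop("cannot remove ", n_remove, " edges without disconnecting (cyclomatic budget ",
         n_cyc, ")")
  edges <- net$edges
  removed <- 0L
  candidates <- sample(seq_len(nrow(edges)))
  alive <- rep(TRUE, nrow(edges))
  ii <- match(edges$from, net$nodes$id); jj <- match(edges$to, net$nodes$id)
  for (e in candidates) {
    if (removed == n_remove) break
    alive[e] <- FALSE
    g <- igraph::make_graph(rbind(ii[alive], jj[alive]), n = nrow(net$nodes),
                            directed = FALSE)
    if (igraph::is_connected(g)) removed <- removed + 1L else alive[e] <- TRUE
  }
  if (removed < n_remove)
    stop("could only remove ", removed, " of ", n_remove,
         " edges without disconnecting")
  out <- net
  out$edges <- edges[alive, ]
  attr(out, "node_index") <- NULL
  out
}

#' Place reactive (partially absorbing) edges at random
#'
#' Selects `n` edges uniformly at random without replacement among edges
#' whose midpoint lies within `max_radial_distance` of the network center,
#' and assigns each the first-order reaction rate `gamma`. Models scattered
#' reactive regions (e.g. ER exit sites) with finite reaction kinetics.
#'
#' @param net a `spatial_network`.
#' @param n number of reactive edges.
#' @param max_radial_distance eligibility radius for edge midpoints
#'   (\eqn{\mu m}); `Inf` makes every edge eligible.
#' @param gamma reaction rate on each selected edge (1/s).
#' @param center network center, default attribute `center` or `c(0,0)`.
#' @return a [target_set()] with the selected reactive edges.
#' @export
select_reactive_edges <- function(net, n, max_radial_distance = Inf, gamma = 1,
                                  center = NULL) {
  if (is.null(center)) center <- attr(net, "center")
  if (is.null(center)) center <- c(0, 0)
  mid <- edge_midpoints(net)
  r <- sqrt((mid[, 1] - center[1])^2 + (mid[, 2] - center[2])^2)
  elig <- which(r <= max_radial_distance)
  if (length(elig) < n)
    stop("only ", length(elig), " edges within radius ", max_radial_distance,
         ", need ", n)
  pick <- if (length(elig) == n) elig else sample(elig, n)
  target_set(edges = data.frame(edge = net$edges$id[pick], gamma = gamma))
}
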