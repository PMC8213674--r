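#' Spatial tubular network
#'
#' A spatial network consists of point-like nodes embedded in the plane (or in
#' 3D) connected by one-dimensional edges (tubules) of physical length
#' \eqn{\ell_{ij}} (\eqn{\mu m}). Edges may be curved and therefore longer
#' than the Euclidean distance between their endpoints, but never shorter.
#' Particles diffuse along the edges; nodes are volume-less intersections.
#'
#' @param nodes data.frame with columns `id` (non-negative integer), `x`, `y`
#'   and optionally `z` (coordinates in \eqn{\mu m}).
#' @param edges data.frame with columns `id`, `from`, `to` (node ids) and
#'   optionally `length` (\eqn{\mu m}). Missing lengths default to the
#'   Euclidean distance between the endpoint positions.
#' @param validate logical; run [net_validate()] on the result.
#'
#' @return An object of class `spatial_network`: a list with data.frames
#'   `nodes` and `edges`, with lengths filled in.
#' @export
#' @examples
#' net <- spatial_network(
#'   nodes = data.frame(id = 0:2, x = c(0, 1, 2), y = 0),
#'   edges = data.frame(id = 1:2, from = c(0, 1), to = c(1, 2))
#' )
#' net_distance(net, 0, 2)
spatial_network <- function(nodes, edges, validate = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "x", "y") %in% names(nodes)))
    stop("nodes needs columns id, x, y")
  if (!all(c("id", "from", "to") %in% names(edges)))
    stop("edges needs columns id, from, to")
  nodes <- nodes[, intersect(c("id", "x", "y", "z"), names(nodes)), drop = FALSE]
  if (is.null(nodes$z)) nodes$z <- 0
  nodes$id <- as.integer(nodes$id)
  edges$id <- as.integer(edges$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  ii <- match(edges$from, nodes$id)
  jj <- match(edges$to, nodes$id)
  if (anyNA(ii) || anyNA(jj)) {
    bad <- unique(c(edges$from[is.na(ii)], edges$to[is.na(jj)]))
    stop("edge references undeclared node id(s): ", paste(bad, collapse = ", "))
  }
  eu <- sqrt((nodes$x[ii] - nodes$x[jj])^2 + (nodes$y[ii] - nodes$y[jj])^2 +
               (nodes$z[ii] - nodes$z[jj])^2)
  if (is.null(edges$length)) edges$length <- eu
  edges$length[is.na(edges$length)] <- eu[is.na(edges$length)]
  edges <- edges[, c("id", "from", "to", "length")]
  net <- structure(list(nodes = nodes, edges = edges), class = "spatial_network")
  if (validate) net_validate(net)
  net
}

#' Validate a spatial network
#'
#' Checks referential integrity, positive lengths, the curved-edge rule
#' (\eqn{\ell \ge} Euclidean endpoint distance, up to a small tolerance for
#' straight edges), duplicate ids, and that the network has at least one edge.
#'
#' @param net a `spatial_network`.
#' @param tol relative tolerance for the curved-edge check.
#' @return `net`, invisibly. Errors describe the first problem found.
#' @export
net_validate <- function(net, tol = 1e-8) {
  nodes <- net$nodes; edges <- net$edges
  if (nrow(edges) < 1) stop("network has no edges")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(edges$id)) stop("duplicate edge ids")
  ii <- match(edges$from, nodes$id); jj <- match(edges$to, nodes$id)
  if (anyNA(ii) || anyNA(jj)) stop("edge references undeclared node id")
  if (any(!is.finite(edges$length)) || any(edges$length <= 0))
    stop("non-positive or non-finite edge length (edge id ",
         edges$id[which(!is.finite(edges$length) | edges$length <= 0)[1]], ")")
  eu <- sqrt((nodes$x[ii] - nodes$x[jj])^2 + (nodes$y[ii] - nodes$y[jj])^2 +
               (nodes$z[ii] - nodes$z[jj])^2)
  short <- edges$length < eu * (1 - tol) - 1e-12
  if (any(short))
    stop("edge ", edges$id[which(short)[1]],
         " is shorter than the Euclidean distance between its endpoints")
  invisible(net)
}

#' @export
print.spatial_network <- function(x, ...) {
  deg <- tabulate(node_index(x)$deg + 1L)
  cat(sprintf("spatial_network: %d nodes, %d edges, total length %.4g um\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length)))
  cat(sprintf("  mean edge length %.4g um; degree range %d-%d\n",
              mean(x$edges$length), min(node_index(x)$deg), max(node_index(x)$deg)))
  invisible(x)
}

# Internal dense indexing: adjacency in slot order. Cached on the object via
# attribute so repeated assemblies don't rebuild it.
node_index <- function(net) {
  idx <- attr(net, "node_index")
  if (!is.null(idx)) return(idx)
  n <- nrow(net$nodes)
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  deg <- tabulate(c(ii, jj), nbins = n)
  # long-format incidence: one row per (node, incident edge)
  inc_node <- c(ii, jj)
  inc_edge <- c(seq_len(nrow(net$edges)), seq_len(nrow(net$edges)))
  inc_opp <- c(jj, ii)
  o <- order(inc_node, inc_edge)
  list(n = n, ii = ii, jj = jj, deg = deg,
       inc_node = inc_node[o], inc_edge = inc_edge[o], inc_opp = inc_opp[o],
       inc_len = net$edges$length[inc_edge[o]])
}

with_index <- function(net) {
  if (is.null(attr(net, "node_index"))) attr(net, "node_index") <- node_index(net)
  net
}

as_igraph <- function(net) {
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  igraph::add_edges(g, rbind(ii, jj))
}

#' Read a spatial network from a plain-text file
#'
#' The format is one record per line, `#` starts a comment:
#' \preformatted{
#' NODE <id> <x> <y> [<z>]
#' EDGE <id> <node1> <node2> [<length>]
#' }
#' Lengths omitted in the file default to the Euclidean distance between the
#' endpoints; explicit lengths longer than that are accepted (curved tubules).
#'
#' @param path file path.
#' @return a validated `spatial_network`.
#' @export
net_read <- function(path) {
  raw <- readLines(path)
  nodes <- list(); edges <- list()
  for (ln in seq_along(raw)) {
    line <- sub("#.*$", "", raw[ln])
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    kw <- toupper(tok[1])
    if (kw == "NODE") {
      if (length(tok) < 4)
        stop("line ", ln, ": NODE needs at least id x y")
      v <- suppressWarnings(as.numeric(tok[2:length(tok)]))
      if (anyNA(v)) stop("line ", ln, ": non-numeric NODE field")
      nodes[[length(nodes) + 1]] <- c(v, 0)[1:4]
    } else if (kw == "EDGE") {
      if (length(tok) < 4)
        stop("line ", ln, ": EDGE needs at least id node1 node2")
      v <- suppressWarnings(as.numeric(tok[2:length(tok)]))
      if (anyNA(v)) stop("line ", ln, ": non-numeric EDGE field")
      edges[[length(edges) + 1]] <- c(v, NA)[1:4]
    } else stop("line ", ln, ": unknown record '", tok[1], "'")
  }
  if (length(nodes) == 0) stop("no NODE records in ", path)
  nd <- as.data.frame(do.call(rbind, nodes))
  names(nd) <- c("id", "x", "y", "z")
  ed <- as.data.frame(do.call(rbind, edges))
  if (nrow(ed)) names(ed) <- c("id", "from", "to", "length")
  spatial_network(nd, ed)
}

#' Write a spatial network to the plain-text format
#'
#' Positions and lengths are written with 15 significant digits so that a
#' save/load round trip reproduces them to at least 12 digits.
#'
#' @param net a `spatial_network`.
#' @param path output file path.
#' @export
net_write <- function(net, path) {
  fmt <- function(v) formatC(v, format = "g", digits = 15)
  con <- file(path, "w"); on.exit(close(con))
  has_z <- any(net$nodes$z != 0)
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    writeLines(paste("NODE", nd$id, fmt(nd$x), fmt(nd$y),
                     if (has_z) fmt(nd$z) else NULL, collapse = " "), con)
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    writeLines(paste("EDGE", e$id, e$from, e$to, fmt(e$length)), con)
  }
  invisible(path)
}

#' Normalize a network: remove self-loops and parallel edges
#'
#' The node-neighborhood propagator assumes each edge of a neighborhood leads
#' to a distinct adjacent node. Degree-2 nodes are transparent to diffusion,
#' so self-loops and parallel edges can be removed without changing the
#' physics by inserting interior degree-2 nodes: each self-loop becomes a
#' chain of two new nodes, each parallel edge gets one interior node. Total
#' tube length is conserved exactly; inserted nodes get interpolated
#' positions. Simple networks are returned unchanged; the operation is
#' idempotent.
#'
#' @param net a `spatial_network`.
#' @return a simple `spatial_network`.
#' @export
net_normalize <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  next_node <- max(nodes$id) + 1L
  next_edge <- max(edges$id) + 1L
  out_edges <- list(); drop <- logical(nrow(edges))
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  first_of_pair <- !duplicated(key)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    ii <- match(e$from, nodes$id); jj <- match(e$to, nodes$id)
    if (e$from == e$to) {
      # self-loop -> A - n1 - n2 - A, thirds of the loop length
      p <- nodes[ii, ]
      n1 <- next_node; n2 <- next_node + 1L; next_node <- next_node + 2L
      # offset interpolated positions slightly off the node so they are distinct
      r <- e$length / (2 * pi)
      nodes <- rbind(nodes, data.frame(id = c(n1, n2),
                                       x = p$x + r * cos(c(1, 2) * 2 * pi / 3),
                                       y = p$y + r * sin(c(1, 2) * 2 * pi / 3),
                                       z = p$z))
      out_edges[[length(out_edges) + 1]] <- data.frame(
        id = next_edge + 0:2, from = c(e$from, n1, n2), to = c(n1, n2, e$to),
        length = rep(e$length / 3, 3))
      next_edge <- next_edge + 3L
      drop[i] <- TRUE
    } else if (dup[i] && !first_of_pair[i]) {
      # later copies of a parallel bundle: split with one interior node
      pi_ <- nodes[ii, ]; pj <- nodes[jj, ]
      nn <- next_node; next_node <- next_node + 1L
      # midpoint, nudged perpendicular so parallel copies don't coincide
      dx <- pj$x - pi_$x; dy <- pj$y - pi_$y
      nrm <- sqrt(dx^2 + dy^2); if (nrm == 0) nrm <- 1
      off <- 0.05 * e$length * i / nrm
      nodes <- rbind(nodes, data.frame(id = nn, x = (pi_$x + pj$x) / 2 - dy * off,
                                       y = (pi_$y + pj$y) / 2 + dx * off,
                                       z = (pi_$z + pj$z) / 2))
      out_edges[[length(out_edges) + 1]] <- data.frame(
        id = next_edge + 0:1, from = c(e$from, nn), to = c(nn, e$to),
        length = rep(e$length / 2, 2))
      next_edge <- next_edge + 2L
      drop[i] <- TRUE
    }
  }
  if (!any(drop)) return(net)
  edges <- rbind(edges[!drop, ], do.call(rbind, out_edges))
  spatial_network(nodes, edges, validate = FALSE)
}

#' Shortest network distance between two nodes
#'
#' The network distance is the shortest distance measured along the edges of
#' the network (sum of edge lengths along the shortest path).
#'
#' @param net a `spatial_network`.
#' @param from,to node ids (`to` may be a vector).
#' @return distance(s) in \eqn{\mu m}. Errors if a pair is disconnected.
#' @export
net_distance <- function(net, from, to) {
  g <- as_igraph(net)
  a <- match(from, net$nodes$id); b <- match(to, net$nodes$id)
  if (anyNA(a) || anyNA(b)) stop("unknown node id")
  d <- igraph::distances(g, v = a, to = b, weights = net$edges$length)
  d <- as.vector(d)
  if (any(!is.finite(d))) stop("nodes are in different connected components")
  d
}

#' Network summary statistics
#'
#' @param net a `spatial_network`.
#' @return list with node/edge counts, total and mean edge length, and the
#'   degree histogram (named vector).
#' @export
net_info <- function(net) {
  idx <- node_index(net)
  dh <- table(factor(idx$deg, levels = 0:max(idx$deg)))
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       total_length = sum(net$edges$length),
       mean_edge_length = mean(net$edges$length),
       degree_histogram = dh)
}

# largest connected component, preserving ids
largest_component <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  keep_ids <- net$nodes$id[keep]
  e <- net$edges[net$edges$from %in% keep_ids & net$edges$to %in% keep_ids, ]
  spatial_network(net$nodes[keep, ], e, validate = FALSE)
}

edge_midpoints <- function(net) {
  ii <- match(net$edges$from, net$nodes$id)
  jj <- match(net$edges$to, net$nodes$id)
  cbind(x = (net$nodes$x[ii] + net$nodes$x[jj]) / 2,
        y = (net$nodes$y[ii] + net$nodes$y[jj]) / 2)
}
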