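#' Target set: absorbing nodes and reactive edges
#'
#' Targets for first-passage calculations: perfectly absorbing nodes
#' (instantaneous, diffusion-limited capture) and/or partially reactive edges
#' carrying a first-order reaction rate \eqn{\gamma} (1/s), modeling
#' reactions that are not diffusion limited.
#'
#' @param nodes integer vector of absorbing node ids (may be empty).
#' @param edges `NULL` or a data.frame with columns `edge` (edge id) and
#'   `gamma` (rate, 1/s).
#' @return an object of class `target_set`.
#' @export
target_set <- function(nodes = integer(0), edges = NULL) {
  nodes <- as.integer(nodes)
  if (!is.null(edges)) {
    stopifnot(is.data.frame(edges), all(c("edge", "gamma") %in% names(edges)))
    stopifnot(all(edges$gamma >= 0))
  }
  structure(list(nodes = nodes, edges = edges), class = "target_set")
}

#' Start distributions
#'
#' `start_nodes()` places the particle on nodes with the given weights
#' (uniform by default); `start_edges()` starts it uniformly distributed
#' along edges, with per-edge weights (proportional to edge length by
#' default, i.e. spatially uniform over the tubules). The string
#' `"edge-uniform"` is accepted wherever a start distribution is expected
#' and is equivalent to `start_edges()`.
#'
#' @param ids node ids.
#' @param weights probabilities (normalized internally).
#' @return an object of class `start_spec`.
#' @export
start_nodes <- function(ids, weights = NULL) {
  ids <- as.integer(ids)
  if (is.null(weights)) weights <- rep(1, length(ids))
  stopifnot(length(weights) == length(ids), all(weights >= 0), sum(weights) > 0)
  structure(list(mode = "nodes", ids = ids, weights = weights / sum(weights)),
            class = "start_spec")
}

#' @rdname start_nodes
#' @param edge_ids edge ids (`NULL` = all edges).
#' @export
start_edges <- function(edge_ids = NULL, weights = NULL) {
  structure(list(mode = "edges", ids = edge_ids, weights = weights),
            class = "start_spec")
}

as_start_spec <- function(start, net) {
  if (is.character(start) && identical(start, "edge-uniform"))
    start <- start_edges()
  if (!inherits(start, "start_spec")) stop("not a start specification")
  if (start$mode == "nodes") {
    if (!all(start$ids %in% net$nodes$id)) stop("start node not in network")
    return(start)
  }
  ids <- if (is.null(start$ids)) net$edges$id else as.integer(start$ids)
  if (!all(ids %in% net$edges$id)) stop("start edge not in network")
  w <- start$weights
  if (is.null(w)) w <- net$edges$length[match(ids, net$edges$id)]
  stopifnot(length(w) == length(ids), all(w >= 0), sum(w) > 0)
  structure(list(mode = "edges", ids = ids, weights = w / sum(w)),
            class = "start_spec")
}

# per-edge gamma vector (dense edge order) from a target set
edge_gamma <- function(net, targets) {
  g <- numeric(nrow(net$edges))
  if (!is.null(targets$edges)) {
    m <- match(targets$edges$edge, net$edges$id)
    if (anyNA(m)) stop("reactive edge id not in network")
    g[m] <- g[m] + targets$edges$gamma
  }
  g
}

# Assemble the network-level Laplace-domain hopping system at Laplace
# variable s (real >= 0 or complex): the substochastic hopping matrix P
# (rows/columns of absorbing target nodes removed), survival vector Q, and
# the edge-start flux matrix PE / survival vector QE. `denom` is the
# per-node propagator denominator sum_j alpha_ij coth(alpha_ij l_ij), also
# used by the maturation density.
assemble_system <- function(net, targets, D, s = 0, with_edges = TRUE) {
  idx <- node_index(net)
  gamma <- edge_gamma(net, targets)
  tnodes <- match(targets$nodes, net$nodes$id)
  if (anyNA(tnodes)) stop("absorbing target node not in network")
  keep <- rep(TRUE, idx$n); keep[tnodes] <- FALSE
  kmap <- cumsum(keep); kmap[!keep] <- NA_integer_
  a <- sqrt((s + gamma[idx$inc_edge]) / D)
  co <- fcoth(a, idx$inc_len)
  th <- ftanh_half(a, idx$inc_len)
  denom <- as.vector(rowsum(cbind(Re(co), Im(co)), idx$inc_node) %*% c(1, 1i))
  if (!is.complex(s)) denom <- Re(denom)
  Qall <- as.vector(rowsum(cbind(Re(th), Im(th)), idx$inc_node) %*% c(1, 1i)) /
    (D * denom)
  if (!is.complex(s)) Qall <- Re(Qall)
  pv <- fsinh_ratio(a, idx$inc_len) / denom[idx$inc_node]
  ok <- keep[idx$inc_node] & keep[idx$inc_opp]
  nk <- sum(keep)
  Pm <- Matrix::sparseMatrix(i = kmap[idx$inc_node[ok]], j = kmap[idx$inc_opp[ok]],
                             x = if (is.complex(s)) Re(pv[ok]) else pv[ok],
                             dims = c(nk, nk))
  Pi <- if (is.complex(s))
    Matrix::sparseMatrix(i = kmap[idx$inc_node[ok]], j = kmap[idx$inc_opp[ok]],
                         x = Im(pv[ok]), dims = c(nk, nk)) else NULL
  # edge starts: flux to each bounding node, survival on edge
  if (with_edges) {
    el <- net$edges$length
    am <- sqrt((s + gamma) / D)
    th_e <- ftanh_half(am, el)
    pe <- th_e / el
    u <- s + gamma
    small <- Mod(am * el) < 1e-4
    qe <- th_e * 0
    if (any(small)) {
      z2 <- (am * el)[small]^2
      qe[small] <- el[small]^2 / (12 * D) * (1 - z2 / 10)
    }
    if (any(!small)) qe[!small] <- (1 - 2 * th_e[!small] / el[!small]) / u[!small]
    ir <- c(seq_len(nrow(net$edges)), seq_len(nrow(net$edges)))
    jc <- c(idx$ii, idx$jj)
    oke <- keep[jc]
    PE <- Matrix::sparseMatrix(i = ir[oke], j = kmap[jc[oke]],
                               x = if (is.complex(s)) Re(rep(pe, 2)[oke]) else rep(pe, 2)[oke],
                               dims = c(nrow(net$edges), nk))
  } else {
    PE <- NULL; qe <- NULL; pe <- NULL
  }
  list(idx = idx, gamma = gamma, keep = keep, kmap = kmap, nk = nk,
       P = Pm, P_im = Pi, Q = Qall[keep], Qall = Qall, denom = denom,
       PE = PE, QE = qe, pe = pe, s = s)
}

# derivative matrices dP/ds, dQ/ds, dPE/ds, dQE/ds at s = 0
assemble_derivatives <- function(net, targets, D, sys) {
  idx <- sys$idx
  if (all(sys$gamma == 0)) {
    len <- idx$inc_len
    S1 <- rowsum(1 / len, idx$inc_node)[, 1]
    S2 <- rowsum(len, idx$inc_node)[, 1]
    S4 <- rowsum(len^3, idx$inc_node)[, 1]
    dpv <- -(1 / (6 * D)) * (len / S1[idx$inc_node] +
                               2 * S2[idx$inc_node] / (len * S1[idx$inc_node]^2))
    dQall <- -(1 / (24 * D^2)) * (S4 / S1 + 4 * S2^2 / S1^2)
    dpe <- -net$edges$length^2 / (24 * D)
    dqe <- -net$edges$length^4 / (120 * D^2)
  } else {
    h <- cstep_h(D, max(net$edges$length))
    sysc <- assemble_system(net, targets, D, s = complex(real = 0, imaginary = h))
    # complex-step: Im of entries / h
    dQall <- Im(sysc$Qall) / h
    dpe <- Im(sysc$pe) / h
    dqe <- Im(sysc$QE) / h
    ok <- sys$keep[idx$inc_node] & sys$keep[idx$inc_opp]
    dP <- sysc$P_im / h
    dPE <- NULL # assembled below from dpe
    dpv <- NULL
  }
  keep <- sys$keep; kmap <- sys$kmap; nk <- sys$nk
  ok <- keep[idx$inc_node] & keep[idx$inc_opp]
  if (is.null(dpv)) {
    dP <- sysc$P_im / h
  } else {
    dP <- Matrix::sparseMatrix(i = kmap[idx$inc_node[ok]], j = kmap[idx$inc_opp[ok]],
                               x = dpv[ok], dims = c(nk, nk))
  }
  ir <- c(seq_len(nrow(net$edges)), seq_len(nrow(net$edges)))
  jc <- c(idx$ii, idx$jj)
  oke <- keep[jc]
  dPE <- Matrix::sparseMatrix(i = ir[oke], j = kmap[jc[oke]],
                              x = rep(dpe, 2)[oke], dims = c(nrow(net$edges), nk))
  list(dP = dP, dQ = dQall[keep], dPE = dPE, dQE = dqe)
}

solve_system <- function(sys) {
  A <- Matrix::Diagonal(sys$nk) - sys$P
  x <- tryCatch(Matrix::solve(A, sys$Q),
                error = function(e) stop("mean first-passage time diverges: no reachable absorbing target or reactive edge", call. = FALSE))
  x <- as.vector(x)
  if (any(!is.finite(x)) || any(x < -1e-8))
    stop("mean first-passage time diverges: no reachable absorbing target or reactive edge")
  x
}

contract_start <- function(net, sys, start, x) {
  if (start$mode == "nodes") {
    di <- match(start$ids, net$nodes$id)
    v <- numeric(sys$nk)
    on_target <- !sys$keep[di]
    if (any(!on_target)) {
      kk <- sys$kmap[di[!on_target]]
      v[kk] <- v[kk] + start$weights[!on_target]
    }
    # start mass on targets contributes tau = 0
    sum(v * x)
  } else {
    me <- match(start$ids, net$edges$id)
    w <- numeric(nrow(net$edges)); w[me] <- start$weights
    as.numeric(sum(w * sys$QE) + sum(w * as.vector(sys$PE %*% x)))
  }
}

#' Laplace-transformed survival probability on the network
#'
#' \eqn{\hat H(s)}: Laplace transform of the probability that a particle with
#' the given start distribution has not yet been absorbed (at a target node
#' or by reaction on a reactive edge). Computed from the matrix expression
#' \eqn{\hat H = V (I - \hat P)^{-1} \hat Q} for node starts, or its two-term
#' edge-start form (particles that never leave the initial edge, plus
#' propagation from the bounding nodes). Rows and columns of absorbing
#' target nodes are removed from the hopping matrix, and the linear system
#' is solved sparsely (no explicit inverse).
#'
#' @param net a `spatial_network`.
#' @param targets a [target_set()].
#' @param start a [start_nodes()]/[start_edges()] spec or `"edge-uniform"`.
#' @param s Laplace variable (scalar, >= 0).
#' @param D diffusivity (\eqn{\mu m^2/s}).
#' @return \eqn{\hat H(s)}. At \eqn{s = 0} this is the mean first-passage
#'   time.
#' @export
survival_transform <- function(net, targets, start, s = 0, D = 1) {
  start <- as_start_spec(start, net)
  if (length(targets$nodes) == 0 &&
      (is.null(targets$edges) || all(targets$edges$gamma == 0)))
    stop("mean first-passage time diverges: no reachable absorbing target or reactive edge")
  sys <- assemble_system(net, targets, D, s, with_edges = start$mode == "edges")
  x <- solve_system(sys)
  contract_start(net, sys, start, x)
}

#' Mean first-passage time to a target set
#'
#' Exact MFPT for a diffusing particle on the network to be absorbed at any
#' target node or react on any reactive edge, evaluated from the \eqn{s=0}
#' closed forms of the propagators (exact linear algebra, no numerical
#' limit). `mfpt_reactive()` is an alias emphasizing the finite-reaction-rate
#' case; both handle absorbing nodes, reactive edges, or a mixture.
#'
#' @inheritParams survival_transform
#' @return mean time (s).
#' @export
#' @examples
#' net <- chain_network(3, 1)
#' mfpt(net, target_set(nodes = 2), start_nodes(0))  # (L^2 - x^2)/(2D) = 2
mfpt <- function(net, targets, start, D = 1) {
  survival_transform(net, targets, start, s = 0, D = D)
}

#' @rdname mfpt
#' @export
mfpt_reactive <- mfpt

#' Mean and variance of the first-passage time
#'
#' The second moment is obtained from the \eqn{s}-derivative of the survival
#' transform at \eqn{s = 0},
#' \eqn{\langle\tau^2\rangle = -2\,\partial_s \hat H|_{s=0}}, evaluated with
#' two sparse linear solves (one right-solve with \eqn{\hat Q}, one
#' left-solve with the start vector). Inert systems use the closed-form
#' propagator derivatives; systems with reactive edges use complex-step
#' differentiation of the reactive transforms.
#'
#' @inheritParams survival_transform
#' @return list with components `mean`, `var`, `sd`, `second_moment`.
#' @export
fpt_variance <- function(net, targets, start, D = 1) {
  start <- as_start_spec(start, net)
  if (length(targets$nodes) == 0 &&
      (is.null(targets$edges) || all(targets$edges$gamma == 0)))
    stop("mean first-passage time diverges: no reachable absorbing target or reactive edge")
  sys <- assemble_system(net, targets, D, 0)
  der <- assemble_derivatives(net, targets, D, sys)
  A <- Matrix::Diagonal(sys$nk) - sys$P
  y <- as.vector(Matrix::solve(A, sys$Q))
  if (any(!is.finite(y)))
    stop("mean first-passage time diverges: no reachable absorbing target or reactive edge")
  rhs <- as.vector(der$dP %*% y) + der$dQ
  if (start$mode == "nodes") {
    di <- match(start$ids, net$nodes$id)
    v <- numeric(sys$nk)
    onk <- sys$keep[di]
    v[sys$kmap[di[onk]]] <- start$weights[onk]
    z <- as.vector(Matrix::solve(Matrix::t(A), v))
    tau <- sum(v * y)
    tau2 <- -2 * sum(z * rhs)
  } else {
    me <- match(start$ids, net$edges$id)
    w <- numeric(nrow(net$edges)); w[me] <- start$weights
    tau <- sum(w * sys$QE) + sum(w * as.vector(sys$PE %*% y))
    z <- as.vector(Matrix::solve(Matrix::t(A), as.vector(Matrix::t(sys$PE) %*% w)))
    tau2 <- -2 * (sum(w * der$dQE) + sum(as.vector(der$dPE %*% y) * w) +
                    sum(z * rhs))
  }
  v2 <- tau2 - tau^2
  list(mean = tau, var = v2, sd = sqrt(max(v2, 0)), second_moment = tau2)
}

#' MFPT for particles with a maturation period
#'
#' Particles diffuse from the start distribution but are initially immature:
#' they cannot react. Maturation is a Poisson process of rate `lambda` (1/s)
#' concurrent with diffusion; once matured, the particle reacts on the
#' reactive edges as usual. The returned time is the mean first-passage time
#' *after* maturation (the mean maturation time `1/lambda` itself is not
#' included): the Laplace-domain spatial density of particles at the moment
#' of maturation is integrated against the post-maturation survival of a
#' point started on each edge, by Gauss-Legendre quadrature per edge with a
#' doubling convergence check.
#'
#' @inheritParams survival_transform
#' @param lambda maturation rate (1/s), > 0.
#' @param quad_n initial Gauss-Legendre points per edge (doubled until the
#'   result changes by < `tol` relative, up to 128).
#' @param tol relative tolerance of the quadrature refinement.
#' @return mean post-maturation first-passage time (s).
#' @export
mfpt_maturation <- function(net, targets, lambda, start, D = 1,
                            quad_n = 16, tol = 1e-8) {
  stopifnot(lambda > 0)
  start <- as_start_spec(start, net)
  if (start$mode != "nodes")
    stop("maturation model requires a node start distribution")
  # immature phase: closed inert network at Laplace variable lambda
  inert <- target_set()
  sys_m <- assemble_system(net, inert, D, s = lambda, with_edges = FALSE)
  idx <- sys_m$idx
  V <- numeric(idx$n)
  V[match(start$ids, net$nodes$id)] <- start$weights
  Am <- Matrix::Diagonal(idx$n) - sys_m$P
  g <- as.vector(Matrix::solve(Matrix::t(Am), V))
  # mature phase: reactive node MFPTs on the full target system
  sys_r <- assemble_system(net, targets, D, s = 0, with_edges = FALSE)
  h <- numeric(idx$n)
  h[sys_r$keep] <- solve_system(sys_r)
  alpha <- sqrt(lambda / D)
  gi <- edge_gamma(net, targets)
  eval_quad <- function(n_q) {
    qcache <- new.env()
    total <- 0
    for (m in seq_len(nrow(net$edges))) {
      l <- net$edges$length[m]
      keyq <- sprintf("%.12g", l)
      gl <- qcache[[keyq]]
      if (is.null(gl)) {
        gl <- pracma::gaussLegendre(n_q, 0, l)
        qcache[[keyq]] <- gl
      }
      y <- gl$x; w <- gl$w
      i <- idx$ii[m]; j <- idx$jj[m]
      psi <- (g[i] * sinh_frac(alpha, l - y, l) / sys_m$denom[i] +
                g[j] * sinh_frac(alpha, y, l) / sys_m$denom[j]) / D
      gm <- gi[m]
      if (gm == 0) {
        ji_ <- 1 - y / l; jj_ <- y / l
        qpt <- y * (l - y) / (2 * D)
      } else {
        ag <- sqrt(gm / D)
        ji_ <- sinh_frac(ag, l - y, l); jj_ <- sinh_frac(ag, y, l)
        qpt <- (1 - ji_ - jj_) / gm
      }
      H <- qpt + ji_ * h[i] + jj_ * h[j]
      total <- total + sum(w * psi * H)
    }
    lambda * total
  }
  t1 <- eval_quad(quad_n)
  n_q <- quad_n
  repeat {
    n_q <- n_q * 2
    t2 <- eval_quad(n_q)
    if (abs(t2 - t1) <= tol * max(abs(t2), .Machine$double.eps)) return(t2)
    if (n_q >= 128) {
      warning("maturation quadrature not converged to tol; returning finest value")
      return(t2)
    }
    t1 <- t2
  }
}

#' Target-averaged global mean first-passage time (tagMFPT)
#'
#' MFPT of a single diffusing particle to a stationary target placed at a
#' network node, averaged over all possible target nodes, with the particle
#' starting uniformly distributed along the network edges. Used as the
#' stationary-target reference for pair-encounter times.
#'
#' @param net a `spatial_network`.
#' @param D diffusivity.
#' @param nodes optional subset of target node ids to average over
#'   (default: all nodes).
#' @return mean time (s).
#' @export
tag_mfpt <- function(net, D = 1, nodes = NULL) {
  if (is.null(nodes)) nodes <- net$nodes$id
  vals <- vapply(nodes, function(v)
    mfpt(net, target_set(nodes = v), start_edges(), D = D), numeric(1))
  mean(vals)
}

#' Per-node MFPT and standard deviation profile
#'
#' Mean and standard deviation of the first-passage time from every
#' non-target node to the target set, computed with two sparse solves (the
#' per-node second moments all come from one extra right-solve).
#'
#' @inheritParams survival_transform
#' @return data.frame with `node` (id), `mean`, `sd` for every node
#'   (targets have 0).
#' @export
mfpt_profile <- function(net, targets, D = 1) {
  sys <- assemble_system(net, targets, D, 0, with_edges = FALSE)
  der <- assemble_derivatives(net, targets, D, sys)
  A <- Matrix::Diagonal(sys$nk) - sys$P
  x <- as.vector(Matrix::solve(A, sys$Q))
  w <- as.vector(Matrix::solve(A, as.vector(der$dP %*% x) + der$dQ))
  tau <- numeric(sys$idx$n); tau[sys$keep] <- x
  m2 <- numeric(sys$idx$n); m2[sys$keep] <- -2 * w
  vv <- pmax(m2 - tau^2, 0)
  data.frame(node = net$nodes$id, mean = tau, sd = sqrt(vv))
}
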