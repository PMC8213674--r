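# Brute-force Brownian-dynamics reference simulator. Used only for
# validation: small fixed Euler steps along edges, uniform redirection at
# nodes, first-order killing on reactive edges. O(sqrt(dt)) biased, so tests
# compare against it at small dt (optionally two dt values).

#' Brownian-dynamics reference first-passage simulator
#'
#' Discrete-time Euler simulation of diffusion along network edges: each
#' step adds a Gaussian increment of standard deviation \eqn{\sqrt{2D\,dt}};
#' a step crossing a node deposits the overshoot onto a uniformly chosen
#' incident edge (including the arrival edge); target nodes absorb;
#' reactive edges kill with per-step survival \eqn{e^{-\gamma dt}}. This is
#' the independent (slow, slightly biased) reference against which the
#' exact analytic and event-driven methods are validated.
#'
#' @param net a `spatial_network`.
#' @param start `list(node = id)` or `list(edge = id, x = coord)`.
#' @param targets a [target_set()] or vector of absorbing node ids.
#' @param D diffusivity.
#' @param dt time step; must satisfy \eqn{\sqrt{2 D dt} \le \min\ell / 20}.
#' @param n_paths number of independent paths.
#' @param tmax censoring horizon.
#' @return data.frame with `time` and `outcome` (`"absorbed"`, `"reacted"`,
#'   `"censored"`).
#' @export
bd_first_passage <- function(net, start, targets, D = 1, dt = 1e-4,
                             n_paths = 1000, tmax = Inf) {
  if (!inherits(targets, "target_set")) targets <- target_set(nodes = targets)
  if (sqrt(2 * D * dt) > min(net$edges$length) / 20)
    stop("dt too large: sqrt(2 D dt) must be <= min edge length / 20")
  idx <- node_index(net)
  adj_ptr <- c(0L, cumsum(idx$deg))
  gamma <- edge_gamma(net, targets)
  tgt <- rep(FALSE, idx$n)
  tgt[match(targets$nodes, net$nodes$id)] <- TRUE
  n <- n_paths
  # state
  if (!is.null(start$node)) {
    v0 <- match(start$node, net$nodes$id)
    if (tgt[v0]) return(data.frame(time = numeric(n), outcome = "absorbed"))
    slots <- (adj_ptr[v0] + 1):adj_ptr[v0 + 1]
    a <- slots[sample.int(length(slots), n, replace = TRUE)]
    m <- idx$inc_edge[a]
    x <- ifelse(idx$ii[m] == v0, 0, net$edges$length[m])
  } else {
    m <- rep(match(start$edge, net$edges$id), n)
    x <- rep(start$x, n)
  }
  alive <- rep(TRUE, n)
  steps <- integer(n)
  outcome <- rep("censored", n)
  t_end <- numeric(n)
  sddt <- sqrt(2 * D * dt)
  len <- net$edges$length
  max_steps <- if (is.finite(tmax)) ceiling(tmax / dt) else .Machine$integer.max
  step <- 0L
  while (any(alive) && step < max_steps) {
    step <- step + 1L
    ia <- which(alive)
    x[ia] <- x[ia] + stats::rnorm(length(ia), 0, sddt)
    # killing on reactive edges
    g <- gamma[m[ia]]
    hasg <- g > 0
    if (any(hasg)) {
      kill <- hasg & stats::runif(length(ia)) < (1 - exp(-g * dt))
      if (any(kill)) {
        ki <- ia[kill]
        alive[ki] <- FALSE
        outcome[ki] <- "reacted"
        t_end[ki] <- step * dt
        ia <- ia[!kill]
      }
    }
    # node crossings (repeat for multiple crossings in one step)
    repeat {
      out_lo <- alive[ia] & x[ia] < 0
      out_hi <- alive[ia] & x[ia] > len[m[ia]]
      cross <- out_lo | out_hi
      if (!any(cross)) break
      ci <- ia[cross]
      v <- ifelse(x[ci] < 0, idx$ii[m[ci]], idx$jj[m[ci]])
      ov <- ifelse(x[ci] < 0, -x[ci], x[ci] - len[m[ci]])
      hit <- tgt[v]
      if (any(hit)) {
        hi_ <- ci[hit]
        alive[hi_] <- FALSE
        outcome[hi_] <- "absorbed"
        t_end[hi_] <- step * dt
      }
      ci <- ci[!hit]; v <- v[!hit]; ov <- ov[!hit]
      if (length(ci)) {
        k <- floor(stats::runif(length(ci)) * idx$deg[v])
        a <- adj_ptr[v] + 1L + as.integer(k)
        me <- idx$inc_edge[a]
        m[ci] <- me
        x[ci] <- ifelse(idx$ii[me] == v, ov, len[me] - ov)
      }
      ia <- ia[alive[ia]]
      if (!length(ia)) break
    }
  }
  data.frame(time = ifelse(outcome == "censored", NA_real_, t_end),
             outcome = outcome)
}

# pair-encounter oracle on a reflecting interval [0, L]: two independent BD
# particles, encounter = separation sign change, with Brownian-bridge
# crossing correction. Test support only.
bd_pair_encounter_interval <- function(L, D = 1, dt = 1e-5, n_pairs = 1000,
                                       x1 = NULL, x2 = NULL, tmax = Inf) {
  n <- n_pairs
  a <- if (is.null(x1)) stats::runif(n, 0, L) else rep_len(x1, n)
  b <- if (is.null(x2)) stats::runif(n, 0, L) else rep_len(x2, n)
  alive <- rep(TRUE, n)
  t_enc <- rep(NA_real_, n)
  sddt <- sqrt(2 * D * dt)
  step <- 0L
  max_steps <- if (is.finite(tmax)) ceiling(tmax / dt) else .Machine$integer.max
  while (any(alive) && step < max_steps) {
    step <- step + 1L
    ia <- which(alive)
    w_old <- b[ia] - a[ia]
    a[ia] <- a[ia] + stats::rnorm(length(ia), 0, sddt)
    b[ia] <- b[ia] + stats::rnorm(length(ia), 0, sddt)
    # reflect at the ends
    a[ia] <- ifelse(a[ia] < 0, -a[ia], a[ia])
    a[ia] <- ifelse(a[ia] > L, 2 * L - a[ia], a[ia])
    b[ia] <- ifelse(b[ia] < 0, -b[ia], b[ia])
    b[ia] <- ifelse(b[ia] > L, 2 * L - b[ia], b[ia])
    w_new <- b[ia] - a[ia]
    crossed <- sign(w_new) != sign(w_old)
    # bridge correction for unobserved crossings (separation diffusivity 2D)
    pb <- exp(-abs(w_old * w_new) / (2 * D * dt))
    crossed <- crossed | (stats::runif(length(ia)) < pb)
    if (any(crossed)) {
      ei <- ia[crossed]
      alive[ei] <- FALSE
      t_enc[ei] <- step * dt
    }
  }
  t_enc
}
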