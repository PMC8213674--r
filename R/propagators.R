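# Laplace-domain propagators for node neighborhoods and edges.
#
# All transforms are functions of alpha = sqrt((s + gamma)/D) through even
# combinations only, so they are analytic in s near 0 and can be evaluated
# for complex s (used for complex-step differentiation of the reactive
# case). The three primitives below are evaluated with small-argument series
# and large-argument exponential forms so that they stay finite from s = 0 up
# to s ~ 1e6 D / l^2.

# alpha / sinh(alpha l): -> 1/l as alpha -> 0
fsinh_ratio <- function(alpha, l) {
  n <- max(length(alpha), length(l))
  alpha <- rep_len(alpha, n); l <- rep_len(l, n)
  z <- alpha * l
  az <- Mod(z)
  out <- alpha # placeholder, correct type/length
  small <- az < 1e-4
  big <- Re(z) > 30
  mid <- !small & !big
  if (any(small)) {
    zs <- z[small]
    out[small] <- (1 - zs^2 / 6 + 7 * zs^4 / 360) / l[small]
  }
  if (any(mid)) out[mid] <- alpha[mid] / sinh(z[mid])
  if (any(big)) {
    zb <- z[big]
    out[big] <- 2 * alpha[big] * exp(-zb) / (1 - exp(-2 * zb))
  }
  out
}

# alpha * coth(alpha l): -> 1/l as alpha -> 0
fcoth <- function(alpha, l) {
  n <- max(length(alpha), length(l))
  alpha <- rep_len(alpha, n); l <- rep_len(l, n)
  z <- alpha * l
  az <- Mod(z)
  out <- alpha
  small <- az < 1e-4
  big <- Re(z) > 30
  mid <- !small & !big
  if (any(small)) {
    zs <- z[small]
    out[small] <- (1 + zs^2 / 3 - zs^4 / 45) / l[small]
  }
  if (any(mid)) out[mid] <- alpha[mid] * cosh(z[mid]) / sinh(z[mid])
  if (any(big)) {
    zb <- z[big]
    out[big] <- alpha[big] * (1 + 2 * exp(-2 * zb) / (1 - exp(-2 * zb)))
  }
  out
}

# (1/alpha) tanh(alpha l / 2): -> l/2 as alpha -> 0
ftanh_half <- function(alpha, l) {
  n <- max(length(alpha), length(l))
  alpha <- rep_len(alpha, n); l <- rep_len(l, n)
  z <- alpha * l / 2
  az <- Mod(z)
  out <- alpha
  small <- az < 1e-4
  mid <- !small
  if (any(small)) {
    zs <- z[small]
    out[small] <- (l[small] / 2) * (1 - zs^2 / 3 + 2 * zs^4 / 15)
  }
  if (any(mid)) out[mid] <- tanh(z[mid]) / alpha[mid]
  out
}

# sinh(alpha x)/sinh(alpha l) for 0 <= x <= l, stable for large Re(alpha l)
sinh_frac <- function(alpha, x, l) {
  n <- max(length(alpha), length(x), length(l))
  alpha <- rep_len(alpha, n); x <- rep_len(x, n); l <- rep_len(l, n)
  z <- alpha * l
  az <- Mod(z)
  out <- alpha * 0 + x / l
  small <- az < 1e-6
  mid <- !small & Re(z) <= 30
  big <- !small & !mid
  if (any(mid)) out[mid] <- sinh(alpha[mid] * x[mid]) / sinh(z[mid])
  if (any(big)) {
    a <- alpha[big]; xx <- x[big]; lb <- l[big]
    out[big] <- exp(a * (xx - lb)) * (1 - exp(-2 * a * xx)) / (1 - exp(-2 * a * lb))
  }
  out
}

#' Node-neighborhood specification
#'
#' A node neighborhood is one node together with its incident edges: the unit
#' on which all local propagators are defined. A particle that has just hit
#' the node diffuses around the incident edges until it first reaches an
#' adjacent node (or reacts on a partially absorbing edge).
#'
#' @param lengths incident edge lengths \eqn{\ell_{i1}..\ell_{id}}
#'   (\eqn{\mu m}), `d >= 1`.
#' @param gamma per-edge first-order reaction rates (1/s), 0 for inert edges.
#' @param D diffusivity (\eqn{\mu m^2/s}).
#' @return an object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(lengths, gamma = 0, D = 1) {
  stopifnot(length(lengths) >= 1, all(lengths > 0), D > 0)
  gamma <- rep_len(gamma, length(lengths))
  stopifnot(all(gamma >= 0))
  structure(list(lengths = as.numeric(lengths), gamma = as.numeric(gamma),
                 D = D, d = length(lengths)),
            class = "neighborhood_spec")
}

#' Laplace-transformed transition-time flux out of a node neighborhood
#'
#' Returns \eqn{\hat P_{ik}(s)}, the Laplace transform of the probability
#' density that a particle starting at the center node first reaches adjacent
#' node `k` (without hitting any other adjacent node or reacting) at lag
#' \eqn{t}:
#' \deqn{\hat P_{ik}(s) = \alpha_{ik} \left[\sinh(\alpha_{ik}\ell_{ik})
#'   \sum_j \alpha_{ij}\coth(\alpha_{ij}\ell_{ij})\right]^{-1},\qquad
#'   \alpha_{ij} = \sqrt{(s+\gamma_{ij})/D}.}
#' With all \eqn{\gamma = 0} this is the inert-neighborhood flux; at
#' \eqn{s = 0} it reduces to the splitting probability
#' \eqn{(1/\ell_{ik})/\sum_j(1/\ell_{ij})}.
#'
#' @param nb a [neighborhood_spec()].
#' @param k exit-edge index (1..d).
#' @param s Laplace variable (vector; real `>= 0`, or complex for
#'   diagnostics/differentiation).
#' @return \eqn{\hat P_{ik}(s)}, same length as `s`.
#' @export
node_flux_laplace <- function(nb, k, s) {
  stopifnot(k >= 1, k <= nb$d)
  vapply(s, function(si) {
    a <- sqrt((si + nb$gamma) / nb$D)
    v <- fsinh_ratio(a[k], nb$lengths[k]) / sum(fcoth(a, nb$lengths))
    if (!is.complex(s) && !is.finite(v)) stop("non-finite flux value at s = ", si)
    v
  }, if (is.complex(s)) complex(1) else numeric(1))
}

#' Laplace-transformed survival probability in a node neighborhood
#'
#' \eqn{\hat Q_i(s)}: transform of the probability that a particle starting
#' at the center node has neither reached an adjacent node nor reacted by
#' time \eqn{t}. Evaluated in the form
#' \deqn{\hat Q_i = \frac{1}{D}\,
#'   \frac{\sum_j \alpha_{ij}^{-1}\tanh(\alpha_{ij}\ell_{ij}/2)}
#'        {\sum_j \alpha_{ij}\coth(\alpha_{ij}\ell_{ij})},}
#' which is identical to \eqn{(1-\sum_k \hat P_{ik})/s} for inert
#' neighborhoods but remains finite at \eqn{s = 0} in general.
#'
#' @inheritParams node_flux_laplace
#' @return \eqn{\hat Q_i(s)}, same length as `s`.
#' @export
node_survival_laplace <- function(nb, s) {
  vapply(s, function(si) {
    a <- sqrt((si + nb$gamma) / nb$D)
    sum(ftanh_half(a, nb$lengths)) / (nb$D * sum(fcoth(a, nb$lengths)))
  }, if (is.complex(s)) complex(1) else numeric(1))
}

#' Splitting probabilities of a node neighborhood
#'
#' Probability that the particle's next node is adjacent node `k`. For an
#' inert neighborhood these are the exact rationals
#' \eqn{P^*_{ik} = (1/\ell_{ik}) / \sum_j (1/\ell_{ij})} and sum to 1. With
#' reactive edges (\eqn{\gamma > 0}) the values sum to less than 1; the
#' deficit \eqn{1 - \sum_k P^*_{ik}} is the probability of reacting before
#' leaving the neighborhood.
#'
#' @param nb a [neighborhood_spec()].
#' @return numeric vector of length `d`.
#' @export
splitting_probabilities <- function(nb) {
  if (all(nb$gamma == 0)) {
    w <- 1 / nb$lengths
    return(w / sum(w))
  }
  vapply(seq_len(nb$d), function(k) node_flux_laplace(nb, k, 0), numeric(1))
}

#' Mean waiting time in a node neighborhood
#'
#' Mean time before the particle leaves the neighborhood (by hitting an
#' adjacent node, or, with reactive edges, by either exit or reaction). For
#' the inert case this is
#' \eqn{Q^*_i = \frac{1}{2D}\sum_j \ell_{ij} / \sum_j (1/\ell_{ij})}; the
#' degree-1 case reduces to the classical \eqn{\ell^2/(2D)} of a reflecting
#' start on an interval.
#'
#' @param nb a [neighborhood_spec()].
#' @return time in seconds.
#' @export
mean_waiting_time <- function(nb) {
  node_survival_laplace(nb, 0)
}

#' Edge specification for edge-start propagators
#'
#' @param length edge length \eqn{\ell_m} (\eqn{\mu m}).
#' @param gamma reaction rate on the edge (1/s).
#' @param D diffusivity (\eqn{\mu m^2/s}).
#' @param x0 optional start coordinate in `[0, length]` (point start).
#' @return an object of class `edge_spec`.
#' @export
edge_spec <- function(length, gamma = 0, D = 1, x0 = NULL) {
  stopifnot(length > 0, gamma >= 0, D > 0)
  if (!is.null(x0)) stopifnot(x0 >= 0, x0 <= length)
  structure(list(length = length, gamma = gamma, D = D, x0 = x0),
            class = "edge_spec")
}

#' Laplace-transformed flux from an edge to its bounding nodes
#'
#' For a point start at `x0` the fluxes to the two boundaries are the
#' classical interval results
#' \eqn{j_- = \sinh[\alpha(\ell - x_0)]/\sinh(\alpha\ell)} (boundary at 0)
#' and \eqn{j_+ = \sinh(\alpha x_0)/\sinh(\alpha\ell)}, with
#' \eqn{\alpha = \sqrt{(s+\gamma)/D}}. For a uniform start the flux to either
#' bounding node is \eqn{\hat P^{(E)} = \tanh(\alpha\ell/2)/(\alpha\ell)};
#' its \eqn{s\to 0, \gamma=0} limit is the trivial splitting probability 1/2.
#'
#' @param edge an [edge_spec()]. If `edge$x0` is set, point-start fluxes are
#'   returned; otherwise the uniform-start flux.
#' @param side `"near"` (boundary at 0) or `"far"` (boundary at `length`);
#'   ignored for the uniform start, where both sides are equal.
#' @param s Laplace variable (vector).
#' @return flux transform value(s).
#' @export
edge_flux_laplace <- function(edge, side = c("near", "far"), s) {
  side <- match.arg(side)
  vapply(s, function(si) {
    a <- sqrt((si + edge$gamma) / edge$D)
    if (is.null(edge$x0)) {
      as.vector(ftanh_half(a, edge$length)) / edge$length
    } else {
      x <- if (side == "near") edge$length - edge$x0 else edge$x0
      as.vector(sinh_frac(a, x, edge$length))
    }
  }, if (is.complex(s)) complex(1) else numeric(1))
}

#' Laplace-transformed survival probability on an edge
#'
#' Uniform start (default): \eqn{\hat Q^{(E)}_m = \frac{1}{\alpha^2 D}
#' [1 - \frac{2}{\alpha\ell}\tanh(\alpha\ell/2)]}; its \eqn{s\to0,\gamma=0}
#' limit is the mean exit time \eqn{\ell^2/(12D)}. Point start at `x0`:
#' \eqn{(1 - j_- - j_+)/(s+\gamma)}, with limit \eqn{x_0(\ell-x_0)/(2D)}.
#'
#' @inheritParams edge_flux_laplace
#' @return survival transform value(s).
#' @export
edge_survival_laplace <- function(edge, s) {
  l <- edge$length
  vapply(s, function(si) {
    u <- si + edge$gamma
    a <- sqrt(u / edge$D)
    if (is.null(edge$x0)) {
      if (Mod(a * l) < 1e-4) {
        z2 <- a^2 * l^2
        as.vector(l^2 / (12 * edge$D) * (1 - z2 / 10))
      } else {
        as.vector((1 - 2 * ftanh_half(a, l) / l) / u)
      }
    } else {
      x0 <- edge$x0
      if (Mod(a * l) < 1e-4) {
        # series of (1 - j- - j+)/u around u = 0
        as.vector(x0 * (l - x0) / (2 * edge$D) *
                    (1 - a^2 * (l^2 + x0 * l - x0^2) / 12))
      } else {
        as.vector((1 - sinh_frac(a, l - x0, l) - sinh_frac(a, x0, l)) / u)
      }
    }
  }, if (is.complex(s)) complex(1) else numeric(1))
}

#' Derivatives of the neighborhood transforms at s = 0
#'
#' `flux_derivative_s0` gives \eqn{\partial\hat P_{ik}/\partial s|_{s=0}} and
#' `survival_derivative_s0` gives \eqn{\partial\hat Q_i/\partial s|_{s=0}}
#' for inert neighborhoods, from the closed-form small-\eqn{s} expansion:
#' \deqn{\partial_s\hat P_{ik}|_0 = -\frac{1}{6D}\left(
#'   \frac{\ell_{ik}}{\Sigma_1} + \frac{2(\Sigma_\ell)}{\ell_{ik}\Sigma_1^2}
#'   \right),\qquad
#'   \partial_s\hat Q_i|_0 = -\frac{1}{24D^2}\left(
#'   \frac{\Sigma_{\ell^3}}{\Sigma_1} + \frac{4\Sigma_\ell^2}{\Sigma_1^2}
#'   \right),}
#' with \eqn{\Sigma_1 = \sum_j 1/\ell_{ij}}, \eqn{\Sigma_\ell = \sum_j
#' \ell_{ij}}, \eqn{\Sigma_{\ell^3} = \sum_j \ell_{ij}^3}. These feed the
#' variance pipeline. For reactive neighborhoods (\eqn{\gamma>0}) no closed
#' form is used; call the `_reactive` complex-step variants instead.
#'
#' @param nb a [neighborhood_spec()] with all `gamma == 0`.
#' @param k exit edge index.
#' @return derivative value.
#' @export
flux_derivative_s0 <- function(nb, k) {
  if (any(nb$gamma != 0))
    stop("closed-form derivative requires an inert neighborhood; use the complex-step variant")
  S1 <- sum(1 / nb$lengths); S2 <- sum(nb$lengths)
  lk <- nb$lengths[k]
  -(1 / (6 * nb$D)) * (lk / S1 + 2 * S2 / (lk * S1^2))
}

#' @rdname flux_derivative_s0
#' @export
survival_derivative_s0 <- function(nb) {
  if (any(nb$gamma != 0))
    stop("closed-form derivative requires an inert neighborhood; use the complex-step variant")
  S1 <- sum(1 / nb$lengths); S2 <- sum(nb$lengths); S4 <- sum(nb$lengths^3)
  -(1 / (24 * nb$D^2)) * (S4 / S1 + 4 * S2^2 / S1^2)
}

# Complex-step derivatives at s = 0 for reactive neighborhoods/edges. The
# transforms are analytic in s (even functions of alpha), so
# f'(0) = Im f(ih)/h to O(h^2) with no subtractive cancellation.
cstep_h <- function(D, lmax) 1e-8 * D / lmax^2

flux_derivative_s0_reactive <- function(nb, k) {
  h <- cstep_h(nb$D, max(nb$lengths))
  Im(node_flux_laplace(nb, k, complex(real = 0, imaginary = h))) / h
}

survival_derivative_s0_reactive <- function(nb) {
  h <- cstep_h(nb$D, max(nb$lengths))
  Im(node_survival_laplace(nb, complex(real = 0, imaginary = h))) / h
}
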