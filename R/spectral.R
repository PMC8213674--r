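# Laplace inversion machinery: poles, residues, time-domain densities and
# exact inverse-transform samplers for node neighborhoods and intervals.

#' Poles of the node-neighborhood flux transform
#'
#' The Laplace-transformed neighborhood flux has simple poles on the negative
#' real axis at \eqn{s_p = -D u_p^2}, where the \eqn{u_p} are the positive
#' roots of \eqn{\sum_j \cot(\ell_{ij} u) = 0}. That sum is strictly
#' decreasing between consecutive singularities \eqn{m\pi/\ell_{ij}} (from
#' \eqn{+\infty} to \eqn{-\infty}), so each interval between *distinct*
#' singularities brackets exactly one root; roots therefore never coincide
#' with the singularities and the residue formula stays well-defined even for
#' equal or commensurate edge lengths.
#'
#' @param nb an inert [neighborhood_spec()] (`gamma` all 0).
#' @param P number of poles to return.
#' @return ascending numeric vector \eqn{u_1 < u_2 < \dots < u_P}
#'   (units 1/\eqn{\mu m}).
#' @export
find_poles <- function(nb, P) {
  if (any(nb$gamma != 0)) stop("pole decomposition requires an inert neighborhood")
  lens <- nb$lengths
  # enough singularities to bracket P roots (root count up to U is ~ U*sum(l)/pi)
  Umax <- (P + 3) * pi / sum(lens) * 1.5 + 2 * pi / min(lens)
  repeat {
    sing <- sort(unique(unlist(lapply(lens, function(l) {
      m <- seq_len(max(1, floor(Umax * l / pi)))
      m * pi / l
    }))))
    # collapse exact duplicates from commensurate lengths
    if (length(sing) > 1) {
      d <- diff(sing)
      sing <- sing[c(TRUE, d > 1e-12 * sing[-1])]
    }
    if (length(sing) >= P + 1) break
    Umax <- Umax * 1.6
  }
  F_ <- function(u) sum(1 / tan(lens * u))
  lo <- c(0, sing[-length(sing)])
  hi <- sing
  roots <- numeric(0)
  for (i in seq_along(hi)) {
    if (length(roots) >= P) break
    a <- lo[i]; b <- hi[i]
    gap <- b - a
    dl <- gap * 1e-8
    fa <- F_(a + dl); fb <- F_(b - dl)
    tries <- 0
    while ((!is.finite(fa) || !is.finite(fb) || fa < 0 || fb > 0) && tries < 40) {
      dl <- dl / 4
      fa <- F_(a + dl); fb <- F_(b - dl)
      tries <- tries + 1
    }
    if (!is.finite(fa) || !is.finite(fb) || fa < 0 || fb > 0)
      stop("pole bracketing failed in interval (", a, ", ", b, ")")
    r <- stats::uniroot(F_, c(a + dl, b - dl), f.lower = fa, f.upper = fb,
                        tol = 1e-13 * b)$root
    roots <- c(roots, r)
  }
  if (length(roots) < P) stop("could not find ", P, " poles (scan bound ", Umax, ")")
  roots
}

#' Residues of the node-neighborhood flux at its poles
#'
#' For pole \eqn{u_p}, the residue of the flux to edge `k` is
#' \deqn{r_p^{(ik)} = \frac{2 D u_p}{\sin(\ell_{ik} u_p)
#'   \sum_j \ell_{ij} \csc^2(\ell_{ij} u_p)}.}
#' The time-domain transition density is then
#' \eqn{P_{ik}(t) = \sum_p r_p^{(ik)} e^{-D u_p^2 t}} and the residues
#' satisfy the normalization \eqn{\sum_p r_p^{(ik)}/(D u_p^2) = P^*_{ik}}.
#'
#' @param nb an inert [neighborhood_spec()].
#' @param k exit edge index.
#' @param poles vector of roots from [find_poles()].
#' @return residues \eqn{r_p^{(ik)}} (units 1/s).
#' @export
residues <- function(nb, k, poles) {
  lens <- nb$lengths; D <- nb$D
  vapply(poles, function(u) {
    2 * D * u / (sin(lens[k] * u) * sum(lens / sin(lens * u)^2))
  }, numeric(1))
}

#' Spectral decomposition of a node neighborhood
#'
#' Computes poles and residues for all incident edges, along with the
#' splitting probabilities and tabulated conditional exit-time CDFs used by
#' the exact samplers. The truncation count `P` defaults to the number of
#' poles needed for the density tail to be negligible down to times of order
#' \eqn{2\times10^{-3}\,\min\ell^2/D}; shorter times carry essentially no
#' exit probability for a node start (the first-passage mass below that time
#' is below \eqn{e^{-125}}).
#'
#' @param nb an inert [neighborhood_spec()].
#' @param P number of poles (`NULL` for the default rule).
#' @param grid_n points in the tabulated CDF grid.
#' @return object of class `spectral_decomposition` with fields `u`
#'   (poles), `R` (P x d residue matrix), `Pstar`, `Qstar`, `lens`, `D`,
#'   and sampling tables.
#' @export
spectral_decomposition <- function(nb, P = NULL, grid_n = 512) {
  lens <- nb$lengths; D <- nb$D
  if (is.null(P)) {
    t_min <- 2e-3 * min(lens)^2 / D
    u_need <- sqrt(46 / (D * t_min))
    P <- ceiling(u_need * sum(lens) / pi) + 5L
  }
  u <- find_poles(nb, P)
  R <- vapply(seq_along(lens), function(k) residues(nb, k, u),
              numeric(length(u)))
  Pstar <- splitting_probabilities(nb)
  Qstar <- mean_waiting_time(nb)
  du2 <- D * u^2
  t_min <- 46 / du2[length(du2)]
  t_max <- 46 / du2[1]
  tg <- exp(seq(log(t_min), log(t_max), length.out = grid_n))
  # conditional exit-time CDF per slot: F_k(t)/Pstar_k
  Eg <- exp(-outer(tg, du2))          # grid_n x P
  W <- sweep(R, 1, du2, "/")          # r / (D u^2), P x d
  cdf <- 1 - sweep(Eg %*% W, 2, Pstar, "/")
  cdf <- pmin(pmax(cdf, 0), 1)
  # enforce monotonicity against fp noise
  cdf <- apply(cdf, 2, cummax)
  structure(list(u = u, R = R, Pstar = Pstar, Qstar = Qstar,
                 lens = lens, D = D, P = P,
                 t_grid = tg, cdf_grid = cdf),
            class = "spectral_decomposition")
}

#' Residue-series normalization check
#'
#' The residues satisfy \eqn{\sum_{p=1}^\infty r_p^{(ik)}/(D u_p^2) =
#' P^*_{ik}}. The raw truncated sum converges only like \eqn{1/u_P} with an
#' oscillating tail, so it is evaluated with vanishing-time regularization:
#' \eqn{\sum_p (r_p/(D u_p^2)) e^{-D u_p^2 t_0} = P^*_{ik} - F_{ik}(t_0)},
#' where \eqn{F_{ik}} is the exit-time CDF through edge k. At the
#' decomposition's shortest resolvable time \eqn{t_0} the damping makes the
#' truncation error negligible (\eqn{\sim e^{-46}}) while
#' \eqn{F_{ik}(t_0) \lesssim e^{-125}} is zero to machine precision, so the
#' result equals the splitting probability essentially exactly.
#'
#' @param decomp a [spectral_decomposition()].
#' @return numeric vector of length `d`: the regularized residue sums,
#'   which equal [splitting_probabilities()] of the neighborhood.
#' @export
residue_normalization <- function(decomp) {
  du2 <- decomp$D * decomp$u^2
  t0 <- 46 / du2[length(du2)]
  as.vector(crossprod(decomp$R / du2, exp(-du2 * t0)))
}

#' Time-domain transition density from the residue series
#'
#' \eqn{P_{ik}(t) = \sum_p r_p^{(ik)} \exp(-D u_p^2 t)}: probability density
#' (per unit time) that the first exit happens at lag `t` through edge `k`.
#' Integrates over all time to the splitting probability \eqn{P^*_{ik}}.
#'
#' @param decomp a [spectral_decomposition()].
#' @param k exit edge index.
#' @param t positive time(s).
#' @return density values.
#' @export
transition_density <- function(decomp, k, t) {
  stopifnot(all(t > 0))
  drop(exp(-outer(t, decomp$D * decomp$u^2)) %*% decomp$R[, k])
}

#' Exact sampling of the neighborhood exit (edge and time)
#'
#' Samples the next adjacent node reached (categorical with the splitting
#' probabilities) and the conditional exit time by inverse-transform
#' sampling of the residue-series CDF (tabulated bracket plus exact-series
#' bisection refinement).
#'
#' @param decomp a [spectral_decomposition()].
#' @param n number of draws.
#' @return data.frame with columns `edge` (slot index) and `dt` (s).
#' @export
sample_exit <- function(decomp, n = 1) {
  res <- cpp_nbhd_sample_exit(decomp$u, decomp$R, decomp$Pstar, decomp$D,
                              decomp$t_grid, decomp$cdf_grid, n)
  data.frame(edge = res[[1]], dt = res[[2]])
}

#' No-passage spatial distribution within a neighborhood
#'
#' `no_passage_cdf()` returns \eqn{Y_{ik}(x, \delta t)}: the probability that
#' the particle is on edge `k` between coordinate `x` and \eqn{\ell_{ik}}
#' (coordinate measured *from the adjacent node*, so this is the mass within
#' distance \eqn{\ell_{ik} - x} of the center node) and has not left the
#' neighborhood by lag `dt`:
#' \deqn{Y_{ik}(x,\delta t) = \sum_p \frac{r_p^{(ik)}}{D u_p^2}
#'  [\cos(u_p x) - \cos(u_p \ell_{ik})] e^{-D u_p^2 \delta t}.}
#' Summed over edges at \eqn{x = 0} it equals the neighborhood survival
#' probability.
#'
#' `sample_no_passage()` draws the particle position at lag `dt` conditional
#' on not having exited: first the edge (weights \eqn{Y_{ik}(0,\delta t)}),
#' then the position along it. Returned positions are distances from the
#' center node.
#'
#' @param decomp a [spectral_decomposition()].
#' @param k edge slot index.
#' @param x coordinate from the adjacent node, in `[0, lens[k]]`.
#' @param dt elapsed time (s).
#' @param n number of draws.
#' @return `no_passage_cdf`: tail mass value. `sample_no_passage`:
#'   data.frame with `edge` (slot) and `r` (distance from center node).
#' @export
no_passage_cdf <- function(decomp, k, x, dt) {
  du2 <- decomp$D * decomp$u^2
  lk <- decomp$lens[k]
  sum(decomp$R[, k] / du2 * (cos(decomp$u * x) - cos(decomp$u * lk)) *
        exp(-du2 * dt))
}

#' @rdname no_passage_cdf
#' @export
sample_no_passage <- function(decomp, dt, n = 1) {
  res <- cpp_nbhd_sample_nopassage(decomp$u, decomp$R, decomp$lens, decomp$D,
                                   dt, n)
  data.frame(edge = res[[1]], r = res[[2]])
}

#' Exact first-passage and no-passage sampling on a finite interval
#'
#' `interval_sample_exit()` draws (side, time) of the first exit of a
#' particle from an interval of length `l` with two absorbing ends, starting
#' at `x0`; side 0 is the end at coordinate 0. `interval_sample_position()`
#' draws the position at lag `dt` conditional on not having exited
#' (no-passage propagation). `refl_interval_sample_*` are the analogues for
#' a particle starting at the reflecting end of an interval with one
#' absorbing end at distance `L` (equivalently, at the center of a symmetric
#' node-segment domain of arm `L`; the exit arm is then uniform among the
#' `d` arms). Densities use the analytic sine/cosine pole series for
#' moderate-to-long times and the image (Gaussian) representation at short
#' times; both are exact to near machine precision in their regimes.
#'
#' @param l,L interval length / arm length.
#' @param x0 start coordinate in `[0, l]`.
#' @param D diffusivity.
#' @param dt elapsed time for no-passage propagation.
#' @param n number of draws.
#' @return data.frames (`side`+`dt`, or `x`, or `dt`, or `r`).
#' @export
interval_sample_exit <- function(l, x0, D = 1, n = 1) {
  res <- cpp_interval_sample_exit(l, x0, D, n)
  data.frame(side = res[[1]], dt = res[[2]])
}

#' @rdname interval_sample_exit
#' @export
interval_sample_position <- function(l, x0, D = 1, dt, n = 1) {
  data.frame(x = cpp_interval_sample_nopassage(l, x0, D, dt, n))
}

#' @rdname interval_sample_exit
#' @export
refl_interval_sample_exit <- function(L, D = 1, n = 1) {
  data.frame(dt = cpp_refl_sample_exit(L, D, n))
}

#' @rdname interval_sample_exit
#' @export
refl_interval_sample_position <- function(L, D = 1, dt, n = 1) {
  data.frame(r = cpp_refl_sample_nopassage(L, D, dt, n))
}
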