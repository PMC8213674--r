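# Small fixture networks built in code.

star_network <- function(d = 3, lens = rep(1, d)) {
  ang <- 2 * pi * (seq_len(d) - 1) / d
  spatial_network(
    nodes = data.frame(id = 0:d,
                       x = c(0, lens * cos(ang)),
                       y = c(0, lens * sin(ang))),
    edges = data.frame(id = seq_len(d), from = 0, to = seq_len(d),
                       length = lens))
}

triangle_network <- function(lens = c(1, 1, 1)) {
  # triangle with possibly curved (longer) edges
  spatial_network(
    nodes = data.frame(id = 0:2, x = c(0, 1, 0.5), y = c(0, 0, 0.4)),
    edges = data.frame(id = 1:3, from = c(0, 1, 2), to = c(1, 2, 0),
                       length = pmax(lens, c(1, sqrt(0.25 + 0.16),
                                             sqrt(0.25 + 0.16)))))
}

# small connected network with irregular (curved) edge lengths, for
# randomized batteries; derived from a honeycomb patch with length jitter
random_network <- function(n_target = 1) {
  net <- honeycomb_patch(1, 6.5, 5.5)
  net$edges$length <- net$edges$length * stats::runif(nrow(net$edges), 1, 1.8)
  attr(net, "node_index") <- NULL
  net
}

# numerical inversion of a Laplace transform by the Abate-Valko fixed
# Talbot contour (test oracle only)
talbot_invert <- function(Fhat, t, M = 48) {
  r <- 2 * M / (5 * t)
  th <- seq_len(M - 1) * pi / M
  ct <- 1 / tan(th)
  s <- r * th * (ct + 1i)
  sig <- th + (th * ct - 1) * ct
  (r / M) * (0.5 * Re(Fhat(r)) * exp(r * t) +
               sum(Re(exp(t * s) * Fhat(s) * (1 + 1i * sig))))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
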