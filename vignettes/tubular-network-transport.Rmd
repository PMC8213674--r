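---
title: "Diffusive transport on tubular networks: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusive transport on tubular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubenet)
```

## The model

Reticulated organelles such as the peripheral endoplasmic reticulum and
fused mitochondrial networks confine diffusing proteins to networks of
narrow tubules. `tubenet` models such a system as a spatial network:
point-like nodes embedded in the plane, connected by one-dimensional edges
of physical length $\ell_{ij}$ (in $\mu m$; edges may be curved and hence
longer than the Euclidean distance between their endpoints). Particles
diffuse along edges with diffusivity $D$ ($\mu m^2/s$) and pass through
nodes instantaneously — junctions have no volume and exert no trapping.
Reactions are represented either by *perfectly absorbing nodes*
(diffusion-limited capture) or by *reactive edges* carrying a first-order
rate $\gamma$ ($s^{-1}$) that acts while the particle is anywhere on the
edge (reaction-limited capture, e.g. entry into an ER exit site).

The particle's state is the last node it crossed. Within that node's
*neighborhood* (the node plus its incident edges) the transition to each
adjacent node $k$ has the Laplace-domain flux

$$\hat P_{ik}(s) = \alpha_{ik}\Big[\sinh(\alpha_{ik}\ell_{ik})
  \sum_j \alpha_{ij}\coth(\alpha_{ij}\ell_{ij})\Big]^{-1},
  \qquad \alpha_{ij} = \sqrt{(s+\gamma_{ij})/D},$$

with companion survival transform $\hat Q_i(s)$. The $s \to 0$ limits give
the splitting probabilities $P^*_{ik} = (1/\ell_{ik})/\sum_j(1/\ell_{ij})$
and mean waiting time $Q^*_i = \frac{1}{2D}\sum_j\ell_{ij}/\sum_j
\ell_{ij}^{-1}$. Network-level first-passage statistics follow from the
substochastic hopping matrix $\mathbf{\hat P}$ with target rows/columns
removed:
$$\hat H(s) = \vec V \cdot (\mathbf I - \mathbf{\hat P})^{-1}\cdot
\hat{\vec Q},\qquad
\tau = \hat H(0), \qquad \langle\tau^2\rangle = -2\,\partial_s\hat H|_0 .$$
Edge-uniform starts add the within-edge terms ($1/2$ splitting,
$\ell^2/12D$ internal time). All solves use sparse LU on
$(\mathbf I-\mathbf{\hat P})$; no inverse is ever formed.

### The second-moment derivative

The variance pipeline needs $\partial_s \hat P_{ik}$ and
$\partial_s \hat Q_i$ at $s = 0$. Expanding the transforms in
$\alpha^2 = s/D$ gives, for an inert neighborhood,

$$\partial_s\hat P_{ik}\big|_0 = -\frac{1}{6D}\left(
  \frac{\ell_{ik}}{\Sigma_1} + \frac{2\,\Sigma_\ell}{\ell_{ik}\Sigma_1^2}
  \right),\qquad
  \partial_s\hat Q_i\big|_0 = -\frac{1}{24D^2}\left(
  \frac{\Sigma_{\ell^3}}{\Sigma_1} + \frac{4\,\Sigma_\ell^2}{\Sigma_1^2}
  \right),$$

with $\Sigma_1 = \sum_j 1/\ell_{ij}$, $\Sigma_\ell = \sum_j \ell_{ij}$,
$\Sigma_{\ell^3} = \sum_j \ell_{ij}^3$. We derived the $\hat Q$ expression
from the expansion of $(1-\sum_k\hat P_{ik})/s$ and verified it against
numerical differentiation and against Brownian-dynamics variances (the
degree-1 case gives $\partial_s\hat Q|_0 = -5/24$ for $\ell = D = 1$,
matching the classical reflecting-interval second moment
$\langle\tau^2\rangle = 5/12$). With reactive edges no closed form is
used; derivatives are computed by complex-step differentiation
($f'(0) = \operatorname{Im} f(ih)/h$), which is exact to $O(h^2)$ with no
subtractive cancellation because every transform is analytic in $s$
through $0$ (they depend on $s$ only through even functions of $\alpha$).

### Maturation

Newly synthesized particles may be unable to react until they mature
(Poisson rate $\lambda$, concurrent with diffusion). The mean
post-maturation capture time is computed by (i) solving the closed, inert
network at Laplace variable $\lambda$ to obtain the spatial density of
particles at the moment of maturation, edge by edge; (ii) composing it with
the post-maturation survival of a point start on each edge (interval
propagators at argument $\gamma_m$, plus reactive node-to-node
propagation); and (iii) integrating the product over every edge with
Gauss–Legendre quadrature (16 points per edge, doubled until the result is
stable to $10^{-8}$ relative, capped at 128). The $\lambda \to \infty$
limit recovers the original start distribution and $\lambda \to 0$ the
length-weighted uniform edge start; both limits are verified to 0.5% in
the test suite.

## Laplace inversion and exact sampling

The flux transform has simple poles at $s_p = -Du_p^2$ where the $u_p$
solve $\sum_j \cot(\ell_{ij}u) = 0$. That function is strictly decreasing
(from $+\infty$ to $-\infty$) on every interval between consecutive
*distinct* singularities $m\pi/\ell_{ij}$, so each interval brackets
exactly one root and no root ever coincides with a singularity — even for
equal or commensurate edge lengths. This removes any need for the length
jitter sometimes used to break commensurate degeneracies; roots are
refined to $10^{-13}$ relative tolerance. Residues follow in closed form,
and the exit-time density through edge $k$ is the series
$P_{ik}(t) = \sum_p r_p^{(ik)} e^{-Du_p^2 t}$.

Truncation: the pole count defaults to the number needed for
$Du_P^2\,t_{\min} \ge 46$ with $t_{\min} = 2\times10^{-3}\min\ell^2/D$.
For a node start, the exit probability before $t_{\min}$ is below
$e^{-125}$, so clamping the sampler at $t_{\min}$ is exact to double
precision. The residue normalization
$\sum_p r_p/(Du_p^2) = P^*_{ik}$ is evaluated with vanishing-time
regularization (damping $e^{-Du_p^2 t_{\min}}$), which converts the
oscillating $1/u_P$ tail into an $e^{-46}$ one.

Sampling is inverse-transform: the exit edge is categorical in $P^*$, and
the conditional exit time solves $F_k(t) = U$ by a table-bracketed
bisection on the exact series (tables hold 512 log-spaced CDF values per
neighborhood class). Interval (two absorbing ends), reflecting-interval,
and no-passage samplers evaluate their CDFs from dual representations:
pole series for dimensionless times $\theta = Dt/\ell^2$ above
0.045 (0.1 for the reflecting case) and image/erfc series below, both
converging with a handful of terms at the switch point. Spatial no-passage
draws use series-CDF bisection at moderate $\theta$ and
Gaussian-proposal rejection against the image density at small $\theta$.

## The event-driven engine

Multi-particle simulations use protective domains:

* **node neighborhood** — particle on a node, all incident edges free;
* **node segment** — particle on a node with equal arms of length $a$
  along each incident edge, bounded by the nearest constraint; by symmetry
  it samples exactly like a reflecting/absorbing interval of length $a$
  with a uniform $1/d$ exit arm;
* **edge segment** — particle (or pair) inside one edge.

The asynchronous loop pops the earliest sampled domain exit, moves that
particle to its boundary, synchronizes only the particles whose domains
touch the reached point (no-passage propagation), rebuilds the affected
domains, and draws fresh exit events. Absorbing targets terminate
particles; for encounter studies the first coincidence of a pair ends the
run. Identical seeds reproduce identical event sequences. The engine's
inner loop is compiled (Rcpp); the R-level `simulate_single()` implements
the same hop/no-passage logic with snapshot synchronization for
trajectory-based analyses (MSD), and the two paths are cross-checked
distributionally in the tests.

### Pair propagation

Two particles sharing an edge segment are propagated jointly. We rotate to
$v = (x_1+x_2)/\sqrt2$ and $w = (x_2-x_1)/\sqrt2$ — two *independent*
coordinates, each diffusing with the same $D$ — and take as the joint
domain an axis-aligned rectangle in $(v, w)$ inscribed in the admissible
triangle $\{w > 0,\ x_1 > a,\ x_2 < b\}$, with $w = 0$ (coincidence)
always one of its faces. The first exit of the rectangle is the minimum of
two independent one-dimensional interval exits, each sampled exactly; the
surviving coordinate is then placed by its no-passage density. Exits
through $w = 0$ are encounters; all other faces are interior
reconfigurations after which the pair (or split singles, when a wall is
closer than the partner) is re-domained. Because every step is an exact
1D first-passage/no-passage draw and the scheme is Markov, the composite
is exact in distribution regardless of how the rectangle is chosen; the
choice only affects efficiency. This construction replaces a
center-of-mass/separation rejection scheme considered during design: the
product form needs no rejection step and reuses the interval samplers
unchanged. It is validated against a fine-step Brownian-dynamics pair
oracle on an interval and on a three-arm junction, and against the
closed-form interval pair-encounter time.

The encounter radius is zero (coincidence of point particles), and the
pair propagator assumes equal diffusivities; unequal-diffusivity pairs are
out of scope.

## Synthetic geometries and study conditions

The generators define the study conditions used throughout the tests and
the acceptance script:

* `honeycomb_band(0.8, 8, 20)` — hexagonal lattice with uniform edge
  length 0.8 um clipped to the annulus between 8 um (nuclear boundary)
  and 20 um (cell boundary), largest component kept, interior degree 3
  (~1270 nodes). "Innermost" nodes (starts for perinuclear synthesis) are
  nodes within one edge length of the inner radius. Reactive-edge
  placement draws uniformly among edges whose *midpoint* lies within a
  maximum radial distance; the "innermost placement" reference confines
  targets to the band where particles originate (midpoint radius
  $\le r_{in} + 1.5\,a$, i.e. edges incident to the origin nodes).
* `chain_network(101, 1)` — the one-dimensional reference geometry.
* `honeycomb_patch(1, 18, 15.5)` — a planar degree-3 lattice of about 200
  nodes for decimation studies; `net_decimate()` removes random edges
  while preserving a single connected component, down to a spanning tree.

These synthetic networks emulate the uniform edge length and low node
degree of tubular organelles but not the features of real, image-derived
networks: heterogeneous edge lengths, curved tubules, irregular boundary
shape, or organelle-specific target densities. Passing tests therefore
validate the algorithms under controlled geometry; they do not by
themselves reproduce organelle-specific numbers, which require extracted
network structures outside this package's scope.

## Numerical choices and degenerate inputs

* Transform primitives are evaluated with small-argument series
  ($|\alpha\ell| < 10^{-4}$) and large-argument exponential forms
  ($\mathrm{Re}\,\alpha\ell > 30$), so evaluations stay finite from
  $s = 0$ up to $s \sim 10^6 D/\ell^2$ (underflowing gracefully to 0).
  The $s = 0$ limits therefore emerge from the same code path as the
  closed forms, with no special-casing at the call sites.
* Self-loops and parallel edges are normalized away by inserting interior
  degree-2 nodes (degree-2 nodes are transparent to the diffusion), which
  conserves total tube length exactly; the propagator then always sees
  distinct adjacent nodes.
* Start mass placed on a target node contributes zero first-passage time.
* Coincident particle positions in `build_domains()` are jittered by
  $10^{-9}\ell$ with a warning; in the encounter rule they count as an
  immediate encounter.
* Bisection tolerances for sampled times and positions are $10^{-12}$
  relative; the Brownian-dynamics oracle enforces
  $\sqrt{2D\,dt} \le \min\ell/20$.

## Problem sizes

The test suite and acceptance script use: $10^4$ simulated pairs on the
101-node chain; 120–800 reactive-edge placements per scan point on the
full band (the placement scan is flat near its optimum, so the optimum
location is extracted from a 3-point moving average of the scan curve);
3000 pairs across twelve spanning-tree realizations of the ~200-node
lattice; $2\times10^4$-draw sampler checks; and Brownian
dynamics oracles of 1200–6000 paths at $dt = 10^{-5}$–$5\times10^{-4}$ s.
These sizes were chosen so each stochastic comparison has 3–4 SEM
resolution against its analytic reference.

## Known limitations

* No luminal flow or drift along edges, no network remodeling, and no
  trapping at voluminous nodes or sheet regions — junctions are ideal
  points.
* The maturation pipeline requires a node start distribution.
* Image-based extraction of networks from micrographs is out of scope;
  real organelle networks can be supplied through the plain-text format.
* Closed-form variance requires inert neighborhoods; with reactive edges
  the derivative is numerical (complex-step), accurate to ~$10^{-8}$
  relative.
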