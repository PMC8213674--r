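# tubenet

Exact first-passage analysis and event-driven stochastic simulation of
particles diffusing on **tubular spatial networks** — the geometry of
reticulated organelles such as the peripheral endoplasmic reticulum and
fused mitochondrial networks, where proteins must diffusively search a web
of one-dimensional tubules for binding partners or localized capture
sites. The package is aimed at quantitative cell biologists and
biophysicists who need reaction-kinetics predictions (mean search times,
their variability, full passage-time distributions, encounter rates
between mobile partners) on networks with physical edge lengths, rather
than on abstract graphs with a single hop timescale.

## What it computes

A network has point-like nodes and edges of length ℓᵢⱼ (μm, possibly
curved); particles diffuse along edges with diffusivity D (μm²/s) and
cross junctions instantaneously. The Laplace-domain flux out of a node's
neighborhood,

    P̂ᵢₖ(s) = αᵢₖ / [ sinh(αᵢₖ ℓᵢₖ) · Σⱼ αᵢⱼ coth(αᵢⱼ ℓᵢⱼ) ],
    αᵢⱼ = sqrt((s + γᵢⱼ)/D),

is the exact transition-time distribution between adjacent nodes,
including optional per-edge reaction rates γ. On top of it the package
provides:

* **Analytic pipeline** (`mfpt()`, `fpt_variance()`, `mfpt_reactive()`,
  `mfpt_maturation()`, `tag_mfpt()`, `mfpt_profile()`): sparse
  matrix expressions Ĥ(s) = V·(I − P̂)⁻¹·Q̂ for survival, mean and
  variance of first-passage times to absorbing nodes and/or partially
  reactive edges, for node or edge-uniform start distributions, including
  a maturation stage (Poisson rate λ) during which particles cannot
  react.
* **Spectral machinery** (`find_poles()`, `residues()`,
  `spectral_decomposition()`, `sample_exit()`, `sample_no_passage()`,
  interval samplers): pole/residue Laplace inversion giving exact
  time-domain transition densities and inverse-transform samplers.
* **Event-driven kinetic Monte Carlo** (`simulate_single()`,
  `simulate_multi()`, `simulate_pair_encounters()`, `fpt_sample()`,
  `extreme_first_passage()`, `msd_from_snapshots()`): exact
  protective-domain simulation with steps spanning whole edges,
  snapshot synchronization, and joint pair propagation with
  zero-radius encounters (compiled inner loop).
* **Geometry** (`honeycomb_band()`, `honeycomb_patch()`,
  `chain_network()`, `net_decimate()`, `select_reactive_edges()`, a
  plain-text `NODE`/`EDGE` file format via `net_read()`/`net_write()`).
* **Validation** (`bd_first_passage()`): an independent brute-force
  Brownian-dynamics reference simulator.

A thin command-line front end is installed at
`system.file("exec", "netprop", package = "tubenet")`.

## Worked example

First-passage from one end of a two-edge chain (nodes at 0, 1, 2 μm,
D = 1 μm²/s) to an absorbing node at the far end, analytically and by
exact simulation:

```r
library(tubenet)
net <- chain_network(3, edge_len = 1)        # 0 -- 1 -- 2
mfpt(net, target_set(nodes = 2), start_nodes(0))
#> [1] 2
fpt_variance(net, target_set(nodes = 2), start_nodes(0))$sd
#> [1] 1.632993
set.seed(1)
fx <- fpt_sample(net, list(node = 0), targets = 2, n = 5000)
mean(fx)
#> [1] 2.014929
```

The analytic value 2 s is the classical (L² − x²)/(2D) with a reflecting
far end; the standard deviation 1.63 s is noticeably smaller than for a
Poisson process of the same mean (which would give 2), and the simulated
mean agrees within its standard error (±0.024).

A reactive-edge example on the ER-like honeycomb band (edge 0.8 μm,
radii 8–20 μm): place 30 partially absorbing edges (γ = 1 s⁻¹) within
12 μm of the center and compute the mean capture time for particles
starting at the innermost nodes:

```r
hb <- honeycomb_band(0.8, 8, 20)
set.seed(1)
tg <- select_reactive_edges(hb, 30, max_radial_distance = 12, gamma = 1)
mfpt(hb, tg, start_nodes(innermost_nodes(hb)))
#> [1] 75.307
```

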