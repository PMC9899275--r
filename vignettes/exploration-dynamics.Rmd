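---
title: "Exploration dynamics of random walks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploration dynamics of random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantity and the model

The territory a random walker explores is usually summarized by $N(t)$, the
number of distinct sites visited up to time $t$. This package is built
around a finer observable: the inter-visit time $\tau_n$, the number of
steps between the first visits to the $n$-th and $(n+1)$-st distinct sites.
The sequence $\{\tau_n\}$ carries the full temporal structure of the
exploration — $N(t)$ is just its inverse — and it is the natural variable
for depletion-controlled processes such as starving foragers, where
survival hinges on whether the *next* new site arrives before a metabolic
deadline.

The key theoretical device is a mapping onto a self-generated trapping
problem: once $n$ sites are visited, the unvisited neighbours of the
support act as traps, and $\tau_n$ is the first-exit time of the walker
from its own visited domain. Unlike the classical trapping problem the
trap configuration ages (it depends on $n$) and is correlated with the
walker's history.

Everything is governed by the ratio
$$\mu = d_f/d_w,$$
where $d_f$ is the fractal dimension of the medium and $d_w$ the walk
dimension ($\langle r^2 \rangle \propto t^{2/d_w}$). The distribution
$F_n(\tau)$ of $\tau_n$ then has up to three regimes:

* an $n$-independent algebraic decay $\tau^{-(1+\mu)}$ for
  $1 \ll \tau \ll t_n$ (absent for transient walks, $\mu > 1$);
* a stretched-exponential regime
  $\exp[-c\,(\tau/t_n)^{\mu/(1+\mu)}]$ for $t_n \ll \tau \ll T_n$
  (absent for recurrent walks, $\mu < 1$, whose two crossovers share the
  same $n$ scale);
* a terminal exponential $\exp[-c\,\tau/n^{1/\mu}]$ beyond $T_n$.

The crossovers are set by the largest trap-free ball in the support: its
typical radius $\rho_n$ scales as $n^{1/d_f}$ (recurrent), $n^{1/(2d_f)}$
(marginal) or stays $O(1)$ (transient), $t_n = \rho_n^{d_w}$, and $T_n$ is
defined by the optimal-fluctuation radius reaching the largest possible
value, $r^*(T_n) = n^{1/d_f}$. `classify_walk()` encodes this regime table;
`survival_bound()` evaluates the optimal-fluctuation lower bound and its
Laplace asymptote with *fitted* constants $a,b$ — only the scalings are
parameter-free, so the package never assumes prefactor values.

## Walk models and substrates

`walk_model()` covers the simple (myopic-ant) walk, persistent walks
(repeat probability $p$, uniform over the $2d-1$ other directions
otherwise), discrete Lévy flights with
$p(s) = 1/[2\zeta(1+\alpha)|s|^{1+\alpha}]$ (flown-over sites are *not*
visited), the 1d true self-avoiding walk (TSAW) with arrival-count
softmax $e^{-C_{i+1}}/(e^{-C_{i+1}}+e^{-C_{i-1}})$, and fractional
Brownian motion discretized to unit intervals of the line.

Substrates: implicit hypercubic lattices ($d \le 6$), the Sierpinski
gasket ($d_f = \ln 3/\ln 2$, $d_w = \ln 5/\ln 2$), the T-fractal tree
($d_f = \ln 3/\ln 2$, $d_w = \ln 6/\ln 2$), and the largest cluster of
critical bond percolation on a periodic square lattice
($d_f = 91/48$; $d_w$ stored as $d_f/0.659$ so that the recorded $\mu$
matches the measured exploration exponent on this medium).

Design choices worth knowing:

* **Finite stand-ins for infinite media.** The gasket is generated at a
  finite generation (default 10, 88575 vertices) with the apex as start
  site; walks that touch the two far corners are flagged through a guard
  set and reported with a warning. At the horizons used here
  (displacement $\sim t^{1/d_w} \approx 50$ lattice units at $t = 10^4$)
  the boundary is never approached.
* **T-tree centre.** The standard T-fractal is built by replacing every
  edge with a "T" of three edges; the start site is the junction created
  at the first subdivision.
* **Percolation identity on the torus.** Bond dilution and cluster
  extraction use the periodic lattice, and site identity is the wrapped
  coordinate: a revisit through the boundary counts as a revisit, which is
  the consistent reading for a finite periodic medium.
* **2d Lévy convention.** The jump *magnitude* follows the printed 1d law
  and the direction is uniform over the four lattice axes, keeping the 1d
  $p(s)$ as the single source of jump lengths.
* **fBM reading.** $\mu = H$ (i.e. $d_f = 1$, $d_w = 1/H$), the reading
  consistent with recurrence for $H < 1$; first entries are detected on
  the sampled positions with no bridge interpolation, matching a
  unit-interval discretization of the line.

## Simulation engine and seeding

The inner loops (steppers, visited-set tracking, $\tau$/$N(t)$/MSD
recorders, boundary-observable trackers, starving foragers, exit-time
propagation) are C++ kernels. Randomness comes from xoshiro256++ seeded by
splitmix64 from the pair (seed, stream), with one stream per realization:
ensembles are bit-reproducible and independent of execution order, and a
single integer seed propagates from `run_config()` through every stage.
R-level stochastic steps (bond dilution, bootstrap, Wang–Landau move
draws) use the R RNG under a locally set and restored seed.

Visited sites are hashed into packed 64-bit keys. The per-dimension bit
budget (full range in 1d, 31 bits in 2d, 21 bits in 3d, 10 bits for
$d \ge 4$) is enforced with explicit errors, so a walk can never silently
alias two sites.

## Exact enumeration

`exit_time_distribution()` propagates the occupation vector through the
transition matrix restricted to the visited domain; mass flowing to any
unvisited neighbour is absorbed as exit probability at that step. This is
exact (mass conserved to $10^{-12}$ per step budget; prefix-stable under
horizon extension) and supports:

* the simple walk on lattices and graph substrates;
* persistent walks, enumerated on the (site, incoming-direction) product
  space, which restores the Markov property exactly; the frozen start has
  no incoming direction, represented as the uniform direction mixture
  (whose next step is exactly uniform);
* 1d Lévy flights with long-range columns; all jumps landing outside the
  domain are exits by definition, so truncating the transition columns at
  the domain extent is exact, not an approximation.

The propagation also records the survival series $S(\tau)$ directly from
the occupation vector (not as $1-\sum F$), so deep tails are accurate in
relative terms down to underflow ($\sim 10^{-300}$) — essential for the
transient-walk tails below. The TSAW and fBM are rejected: they are
history-dependent and have no finite Markov representation on the domain.

Mean exit times solve $(I-Q)m = 1$ with a sparse LU factorization
(`Matrix::solve`). At fixed $n$ the start-averaged mean exit time is
strongly *anti*-correlated with the boundary surface — compact,
small-surface domains hold the walker longest — which is precisely the
observation motivating the rare-event bias below; across $n$ it grows
with the surface.

## Rare-event sampling for transient tails

For transient walks the stretched-exponential and terminal tails are
carried by domains of atypically small surface, exponentially rare under
plain simulation. `wang_landau_domains()` runs a Markov chain whose state
is the *generating trajectory* (guaranteeing every sampled domain is
realizable by the walk): a move keeps a uniformly chosen prefix and
regrows the suffix until $n$ distinct sites are reached, and is accepted
with Wang–Landau weights on the boundary-bond count. Parameters, chosen
where the method needs them and not dictated by any external source:
initial $\ln f = 1$, halving on histogram flatness $\ge 0.8$, a binned
surface window from just below the minimal sphere-like surface
($\approx 4.5\,n^{(d-1)/d}$ bonds) up to the maximum $2dn$, 24 bins by
default (per-integer bins would never flatten: ever-rarer values keep
appearing). Reweighting by $e^{g(s)}$ undoes the flat histogram;
`reweighted_tail()` then averages *exact* per-domain survival curves
(enumeration from the last-visited site) with these weights, reaching
survival probabilities far below $10^{-100}$. Recurrent and marginal
walks are refused: their surface coordinate is degenerate (an interval in
1d) and their tails do not need the bias.

## Estimators

* `fit_power_law()` — log-log least squares on logarithmically binned
  densities (factor 1.25), bootstrap standard errors. Binning matters on
  bipartite lattices, where exact exit masses oscillate with parity;
  `bin_mass_curve()` aggregates enumeration output the same way.
* `estimate_tail_rate()` — slope of the log empirical survival beyond a
  quantile threshold (default 0.9), after discarding tail points carried
  by fewer than 5 samples, whose log-survival noise would dominate the
  fit. For recurrent walks the window sits in the terminal exponential
  regime once the threshold clears the algebraic part (the $\theta_n$
  scaling test uses the 0.99 quantile for this reason).
* `scaling_collapse()` — rescales curves by $X = \tau/n^{x}$,
  $Y = F\,n^{y}$, interpolates onto a common log-grid over the support
  overlap, and scores the mean pairwise squared deviation of $\log Y$;
  exponent fits are grid searches over this score.
* Fit windows are chosen relative to the predicted crossovers with safety
  margins (e.g. the 1d interval exponent on $[5, n^2/10]$, the marginal
  early window below $\sqrt{n}$); boundary-observable exponents need
  windows well above $\tau \approx 100$ before the asymptotic power law
  sets in.

**The marginal $T_n$ exponent.** The terminal exponential of marginal
walks sets in at survival probabilities $\sim e^{-c\sqrt n}$
($\sim 10^{-16}$ already at $n = 100$), beyond any direct sampling. The
package therefore measures the two ingredients of $T_n$'s *definition*
$r^*(T_n) = n^{1/d_f}$ — the $t_n$ exponent from the early-window
collapse and the $\rho_n$ exponent from the trap-free-radius growth — and
combines them as
$T_n\text{-exp} = t_n\text{-exp} + (d_f+d_w)(1/d_f - \rho_n\text{-exp})$.

## What the generators emulate — and what they do not

The simulators *are* the study system: discrete-time, discrete-space
walks on clean lattices, deterministic fractals and critical percolation
clusters. Passing tests therefore demonstrate the universality claims
within that scope. They do not probe continuous-time or continuous-space
motion, heavy-tailed waiting times, biased or interacting walkers, medium
disorder away from criticality, or measurement noise of empirical
trajectories; conclusions about real foraging data inherit only the
regime structure, not the clean exponents.

Problem sizes are desk-scale by design and stated in the tests: e.g.
$n \le 1600$ with $10^4$ realizations for the marginal early exponent, a
$512^2$ percolation cluster with $10^3$ walkers, $3\times 10^4$
realizations for tail rates, $n = 200$ Wang–Landau ensembles. Exponents
carrying logarithmic corrections (marginal crossovers, the starving
forager's $S^2$ law) converge slowly: at the metabolic times swept here
($S \le 64$) the measured lifetime exponent sits visibly below its
asymptote, and the sweep reports what it measures.

## Known limitations

* Persistent-walk enumeration multiplies the state space by $2d$;
  domains beyond a few thousand sites become slow.
* 2d Lévy enumeration (long-range columns in two dimensions) is not
  implemented; transient 2d Lévy statistics come from direct simulation.
* The Wang–Landau surface window is heuristic; pathological `n_bins`
  choices can stall flatness (the run then returns a partial ensemble
  with a warning rather than failing).
* Graph-substrate trap-free radii use the chemical distance, lattice ones
  the Euclidean distance; the two conventions agree only asymptotically.
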