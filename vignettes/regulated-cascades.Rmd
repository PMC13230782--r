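---
title: "Regulated threshold cascades on modular networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulated threshold cascades on modular networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`regcascade` studies complex contagion — spreading that needs social
reinforcement, not just a single exposure — on networks with community
structure, under explicit regulation of transmission.

A network of $N$ nodes is split into $n$ communities (two throughout most of
the package's defaults, called A and B). Each node carries an
intra-community degree $k_{\mathrm{intra}}$ and an inter-community degree
$k_{\mathrm{inter}}$, drawn from per-block degree distributions
$P_{\mathrm{intra}}$ and $P_{\mathrm{inter}}$ with means $z_{\mathrm{intra}}$
and $z_{\mathrm{inter}}$. Community strength is summarized by the mixing
parameter

$$\mu = \frac{z_{\mathrm{inter}}}{z_{\mathrm{intra}} + z_{\mathrm{inter}}},$$

so $\mu = 0$ is two isolated modules, $\mu = 1$ a bipartite graph, and
$\mu = 0.5$ random-like connectivity.

Nodes are susceptible ($x_i = 0$) or adopted ($x_i = 1$); adoption is
irreversible (an early-stage rumor/information model, no recovery). A seed
fraction $\rho_0$ of **all** nodes is placed uniformly inside one community,
so with equal halves the seeded community starts at local density
$2\rho_0$. Updates are synchronous: at every sweep each susceptible node $i$
with total degree $k$ counts its adopted neighbors per channel,
$\mathbf{m} = (m_{\mathrm{intra}}, m_{\mathrm{inter}})$, and adopts iff

$$\mathbf{m} \cdot \boldsymbol{\omega} > \theta k
\qquad \text{(proportional rule)}, \qquad
\mathbf{m} \cdot \boldsymbol{\omega} > C
\qquad \text{(constant rule)},$$

with strict inequality — ties never adopt. The regulation pair
$\boldsymbol\omega = (\omega_{\mathrm{intra}}, \omega_{\mathrm{inter}}) \in
[0,1]^2$ scales within- and cross-community influence;
$1 - \omega$ is the intervention intensity ($\omega = 1$ unregulated,
$\omega = 0$ full suppression). At
$\omega_{\mathrm{intra}} = \omega_{\mathrm{inter}}$ the model collapses to
the classical single-parameter threshold cascade; the package's subject is
what happens off that diagonal. The order parameter is the final adoption
fraction $\rho_\infty$; per-community values $\rho^A_\infty, \rho^B_\infty$
distinguish a *non-diffusive* regime ($\rho_\infty$ near $\rho_0$), a
*localized* regime (the seed community saturates, the other does not;
$\rho_\infty \approx 0.5$ for equal halves), and a *global* regime
($\rho_\infty \approx 1$). Transitions between them are abrupt.

Implementation notes for the simulator (`run_cascade()`): the network's
adjacency is held as a sparse matrix and each sweep is one masked
matrix–vector product per community, so a sweep costs $O(\text{edges})$;
monotonicity guarantees a fixed point in at most $N$ sweeps and in practice
a few dozen. Degree-0 nodes keep their initial state forever. Because the
rule compares floating products, adoption uses a $10^{-9}$ guard on the
strict inequality so that exact ties (e.g. $m\omega = \theta k$ with
$\omega = 1$) never adopt regardless of rounding.

# The tree-like (TL) solver

`tl_fixed_point()` computes $\rho_\infty$ without simulation, assuming the
network is locally tree-like. The auxiliary unknown $y^I$ is the
probability that a node of community $I$, reached along a random link into
$I$, is adopted. For two communities the update for $y^A$ sums over the
joint degree pmf $P_{\mathrm{intra}}(k_i)\,P_{\mathrm{inter}}(k_j)$ with
link-level weight $(k_i + k_j)/z$, split into an intra-cavity part (the
parent sits on an intra link: binomial over $k_i - 1$ intra neighbors at
$y^A$ and $k_j$ inter neighbors at $y^B$) and an inter-cavity part
($k_i$ at $y^A$, $k_j - 1$ at $y^B$), each gated by the threshold rule;
seeds enter additively as $y^A_0 = \rho^A_0$. Iteration from
$y_0 = \rho_0$ is componentwise monotone non-decreasing and bounded by 1,
so it always converges; we stop when the largest change drops below
`tol = 1e-10` (at most `max_iter = 1e4` sweeps, reached only
asymptotically close to a phase boundary). The final densities use the
same sums with full binomials, the full degree, and no cavity decrement,
and the global $\rho_\infty$ is the community-weighted mean. The
normalizing $z$ is the community's own total mean degree (identical to the
global mean in the symmetric models used throughout).

**Which degree enters the threshold inside the recursion.** The cavity
binomials necessarily run over $k - 1$ neighbors (the parent is excluded
from the *count*), but the node being updated still *has* degree $k$, and
in the synchronous dynamics its threshold is always $\theta k$. The
package therefore evaluates the rule at the full degree by default
(`cavity_threshold = "full"`). This is not a cosmetic choice: with
Poisson blocks at $z = 15$, $\mu = 0.5$, $\theta = 0.25$, $\rho_0 = 0.1$,
$\omega_{\mathrm{inter}} = 1$, the full-degree recursion puts the
non-diffusion→global jump at $\omega_{\mathrm{intra}} \approx 0.69$, in
agreement with direct simulation at $N = 2\times10^4$ (jump between 0.6
and 0.7), while evaluating the rule at $\theta(k-1)$ shifts the predicted
jump down to $\approx 0.52$, which the dynamics do not show. The
decremented variant remains available (`cavity_threshold =
"decremented"`) for comparison.

**Two implementations, one contract.** The two-community path runs in
compiled code with the inner double sum over
$(m_{\mathrm{intra}}, m_{\mathrm{inter}})$ reduced to binomial tail
probabilities,
$\sum_{m_{\mathrm{intra}}} \mathcal{B}(m_{\mathrm{intra}})\,
\Pr\!\left[m_{\mathrm{inter}} > (\theta k' - \omega_{\mathrm{intra}}
m_{\mathrm{intra}})/\omega_{\mathrm{inter}}\right]$, with precomputed pmf
and cdf tables built by a mode-centered ratio recurrence (one `dbinom`
call per table row; $\omega_{\mathrm{inter}} = 0$ degenerates to an
indicator on $m_{\mathrm{intra}}$). This makes one update $O(K^3)$ in the
support size $K$ instead of $O(K^4)$. The general $n$-community update
(`tl_update_general()`) is instead a literal pure-R evaluation of the
nested sums, enumerating the weighted adopted-neighbor convolution
exactly; it is the reference implementation, is regression-tested to
agree with the compiled path at $n = 2$ to $10^{-12}$, and serves
three-community models with small degree supports (its cost grows with
the product of support sizes, guarded by `max_terms`).

Degree supports are inherited from `make_distribution()`: Poisson supports
stop at the smallest cutoff leaving at most `truncation_mass = 1e-10` of
upper-tail probability (the headline anchors move by less than $10^{-6}$
when this is tightened or loosened tenfold); discrete power laws are
normalized by direct summation on $[k_{\min}, k_{\max}]$, never by a
zeta-function approximation.

# Regime classification and phase analysis

`classify_regime()` calls a point non-diffusive when every community stays
within `eps_contain` of its seed density, global when every community
exceeds $1 - {}$`eps_saturate`, and localized otherwise. The defaults are
`eps_contain = 0.1` and `eps_saturate = 0.05`. The containment band is
deliberately not tiny: even when a cascade cannot percolate, nodes
adjacent to several seeds adopt, so the non-diffusive plateau sits a few
percent above $\rho_0$ (measured $\rho_\infty \approx 0.124$–$0.153$ at
the $z = 15$, $\theta = 0.25$, $\rho_0 = 0.1$ study point, in both solver
and simulation). Because the transitions are abrupt — the next branch up
is the localized plateau near 0.5 — any band wide enough to cover that
residual local adoption and narrower than the jump yields the same
boundaries to within the bisection tolerance; 0.1 sits comfortably in
that window. `find_critical()` bisects one parameter on the containment
indicator (default width $10^{-3}$), requiring a bracket whose endpoints
disagree. The containment check exploits monotonicity for an early exit:
as soon as an iterate's implied density leaves the band, the point is
uncontained, which makes the uncontained side of every bisection cheap.

# Minimal-cost intervention

The socio-economic cost of a regulation pair is, by default,

$$F(\boldsymbol\omega) = \frac{e^{-(\omega_{\mathrm{intra}} +
\omega_{\mathrm{inter}})} - e^{-2}}{1 - e^{-2}},$$

normalized to $F(1,1) = 0$ (no restriction) and $F(0,0) = 1$ (full
suppression), convex so that near-total blockage is disproportionately
expensive. Linear ($1 - (\omega_{\mathrm{intra}} +
\omega_{\mathrm{inter}})/2$) and quadratic
($((1-\omega_{\mathrm{intra}})^2 + (1-\omega_{\mathrm{inter}})^2)/2$)
forms are provided as robustness alternatives, in their canonical
normalized versions with the same endpoints, to check that the location
of the cost peak does not hinge on the exponential shape.

The controllable region $U_{\mathrm{free}}$ is the set of pairs whose TL
solution stays contained. `controllable_boundary()` traces its upper edge
on an $\omega_{\mathrm{intra}}$ grid (default step 0.01), bisecting the
largest contained $\omega_{\mathrm{inter}}$ to $10^{-4}$; monotonicity of
containment in both entries makes the curve non-increasing, and each
column's bisection is bracketed by the previous column's boundary. Since
$F$ is strictly decreasing in both entries the optimum lies on that
boundary; for the exponential and linear forms the iso-cost contours are
straight lines of slope $-1$, so the optimum is the boundary point
maximizing $\omega_{\mathrm{intra}} + \omega_{\mathrm{inter}}$ (the
tangency of the contour family with the boundary), with ties broken
toward larger $\omega_{\mathrm{intra}}$; the quadratic form is minimized
directly over boundary points. The winner is polished by one local
bisection along $\omega_{\mathrm{intra}}$ and re-verified by a fresh TL
containment solve before being returned.

Scanning $\mu$ with the total degree held fixed
($z_{\mathrm{intra}} = (1-\mu)z$, $z_{\mathrm{inter}} = \mu z$) yields the
package's central result reproduced by `optimal_cost_curve()`: the
minimal cost $F(\boldsymbol\omega_o)$ is unimodal in $\mu$ with its peak
at moderate mixing (argmax 0.45 on the default grid at $z = 20$,
$\theta = 0.1$, $\rho_0 = 0.17$, with a nearly flat top across
$\mu \in [0.45, 0.5]$), and strongly modular or strongly mixed networks
are cheaper to contain. Below the peak the optimum spends its budget on
the intra channel ($\omega_{\mathrm{intra}} < \omega_{\mathrm{inter}}$),
above it on the inter channel. The unimodality flag tolerates
fluctuations of 0.005 in $F$, the scale of the boundary-grid
discretization noise.

# Synthetic data: what it emulates and what it does not

`build_modular_network()` realizes block models by configuration-model
stub matching: per-module intra stub lists and per-pair bipartite inter
stub lists are shuffled and paired, collisions (self-loops, duplicate
edges) are re-paired for up to 100 sweeps, and any leftover stubs are
dropped with a message (a vanishing fraction at the sizes used). Odd
intra stub totals are fixed by incrementing one uniformly chosen node;
unequal bipartite totals by incrementing random nodes on the deficit
side. `rewire_to_mu()` retunes the mixing of an existing network by
double-edge swaps — two intra edges from different modules cross into two
inter edges, or two inter edges between the same pair merge into two
intra edges — so every node's total degree is preserved exactly, stopping
within one edge's worth ($1/|E|$) of the target. The SNAP-dialect fixture
generator (`make_snap_fixture()`) plants two Bernoulli-block communities
with optional overlap plus small peripheral communities, recording its
ground truth in a JSON sidecar, so the whole empirical pipeline (read,
pair selection, overlap assignment, induced subnetwork, statistics,
cascade) is exercised without downloads.

These generators reproduce prescribed degree distributions and block
mixing and nothing else: clustering is vanishing, degrees are
uncorrelated between neighbors, communities do not overlap (outside the
fixture's explicit shared nodes), and edges are static. Passing tests
therefore validate the solvers *on the model class the theory assumes*;
on real networks with triangles, hubs' degree correlations, or temporal
activity, the TL solution is an approximation whose plateau structure —
but not necessarily its exact boundary positions — is expected to
persist, which is also why transitions measured on the bundled empirical
pipeline are somewhat smoother than the block-model ones.

# Numerical choices, edge cases, and problem sizes

* Strict-inequality gating with a $10^{-9}$ tolerance everywhere (R,
  C++), so ties never adopt and binary-float noise cannot flip a gate.
* Seeds: `round(rho0 * N)` nodes, all in the seed community; `rho0` is a
  fraction of all $N$ nodes. The alternative per-community reading
  ($\rho^A_0 = \rho_0$) was checked and rejected: it produces no global
  transition at all in $\omega_{\mathrm{intra}} \in [0.5, 0.9]$ under the
  study conditions, contradicting the observed regime structure.
* Degenerate inputs: $z = 0$ Poisson is a point mass at 0; $\omega = (0,0)$
  yields $\rho_\infty = \rho_0$ exactly in both solver and simulation;
  $\theta = 0$ reduces to single-exposure (SI-like) spreading; $\theta = 1$
  never spreads.
* Test and acceptance problem sizes were chosen as the smallest at which
  the compared quantities are stable: simulations use $N = 2\times10^4$
  (realized block means within 5% of targets, TL–simulation gaps below
  0.02 away from boundaries) with 5–20 realizations; TL supports are the
  truncated ones above (about $10^3$ degree pairs for the Poisson study
  models); the cost curve uses the 0.01/$10^{-4}$ boundary resolution on
  a 17-point $\mu$ grid.

# Known limitations

* **Scale-free calibration.** For fully scale-free blocks the exponent
  $\lambda = 3$ and a mean degree of $z = 20$ cannot hold simultaneously
  with a small minimum degree: a truncated $k^{-3}$ law reaching mean 10
  per channel needs $k_{\min} = 6$ ($k_{\max} = 100$), which leaves no
  low-degree nodes, and the TL global-phase density is then 1.000 (the
  value `calibrate_power_law_mean()` + `tl_fixed_point()` report, and
  which a configuration-model simulation confirms). Constructions that do
  contain low-degree nodes — per-channel $k_{\min} = 1$, or one
  power-law total degree split binomially across channels — give either
  1.000 again or 0.54–0.63, at mean degrees far below 20. Reported
  global-phase densities around 0.8 for such networks therefore depend on
  an unstated generation convention that the package does not attempt to
  reverse-engineer; the mean-matched calibration is the documented
  default and the sensitivity is left visible.
* The TL model assumes independent intra/inter degrees (product-form
  joint pmf) and local tree-likeness; correlated channels can be
  approximated through `empirical_dist()` marginals only.
* The general $n$-community reference solver is exponential in $n$ over
  the degree supports; it is meant for $n = 3$ validation at small
  degrees, not production use at large $n$.
* Recovery dynamics (SIS/SIR), asynchronous updates, time-varying
  regulation, node-heterogeneous thresholds, and finite-size scaling of
  the transitions are out of scope.
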