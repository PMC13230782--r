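# regcascade

Regulated threshold cascades on modular networks.

## What problem this solves

Containing the spread of rumors or misinformation in a social system means
balancing two channels: moderation *within* tightly knit communities and
throttling of the bridges *between* them. `regcascade` is for network
scientists and computational epidemiologists who want to ask, quantitatively:
given a network's community structure, where should regulatory effort go,
how strong must it be, and what does it cost?

The model: a network of `N` nodes in two (or `n`) communities, with
intra- and inter-community degrees drawn from per-block distributions and
community strength summarized by the mixing parameter
`mu = z_inter / (z_intra + z_inter)`. Information spreads as a complex
contagion without recovery: at each synchronous step a susceptible node of
total degree `k` with adopted-neighbor counts `m = (m_intra, m_inter)`
adopts iff

```
m . omega > theta * k        (proportional rule; strict inequality)
```

where `omega = (omega_intra, omega_inter)` are effective transmissibilities
— `1 - omega` is the intervention intensity per channel. (A constant-rule
variant `m . omega > C` is also provided.) Tuning `omega` against `mu`
produces three sharply separated regimes of the final adoption density
`rho_inf`: non-diffusive (`rho_inf ~ rho0`), localized (the seeded
community saturates, `rho_inf ~ 0.5`), and global (`rho_inf ~ 1`).

The package provides:

* degree distributions (Poisson / truncated power law / regular /
  empirical) and a configuration-model generator for modular networks,
  plus degree-preserving rewiring to retune `mu`;
* a fast cascade simulator (sparse-matrix synchronous updates) and
  ensemble statistics;
* a tree-like (message-passing) solver for `rho_inf` — compiled
  two-community fast path, literal n-community reference — with monotone
  fixed-point iteration;
* phase diagrams, regime classification, and bisection for critical
  points;
* a minimal-cost intervention optimizer: traces the boundary of the
  controllable region (where diffusion fails to percolate) and finds the
  regulation pair minimizing an exponential / linear / quadratic cost;
* readers, writers, and a synthetic fixture generator for SNAP-style edge
  lists and ground-truth community files, with community-pair selection
  and overlap assignment for empirical two-community subsystems.

## Worked example

```r
library(regcascade)

# symmetric two-community Poisson model, z = 15, random-like mixing
model <- tl_model_poisson(z = 15, mu = 0.5)

# unregulated: the cascade is system-wide
tl_fixed_point(model, c(1, 1), theta = 0.25, rho0 = 0.1)
#> <tl_result> rho_inf = 1.00000 (1.0000, 1.0000), 9 iterations

# moderate intra regulation contains it near the seed level
tl_fixed_point(model, c(0.6, 1), theta = 0.25, rho0 = 0.1)
#> <tl_result> rho_inf = 0.13443 (0.2088, 0.0601), 33 iterations

# where is the jump? bisection on the containment indicator
find_critical("omega_intra", c(0.5, 0.9), z = 15, theta = 0.25,
              rho0 = 0.1, omega_inter = 1, mu = 0.5)
#> [1] 0.6878906

# the simulator agrees: N = 2e4 realization of the same model
set.seed(1)
net <- build_modular_network(c(10000, 10000), poisson_dist(7.5), poisson_dist(7.5))
net
#> <modular_network> N = 20000, modules = 2 (10000+10000), edges = 149957, z = 14.996, mu = 0.4984
set.seed(2)
run_cascade(net, c(0.6, 1), contagion_config(theta = 0.25, rho0 = 0.1))
#> <cascade_trajectory> steps = 10, rho_inf = 0.1366 (0.210, 0.064)

# cheapest regulation that still contains a strongly modular network:
# the optimum regulates the intra channel much harder than the bridges
optimal_intervention(tl_model_poisson(20, 0.2), theta = 0.1, rho0 = 0.17,
                     grid_step = 0.05)
#> <intervention_result> omega_o = (0.1000, 0.7000), exponential cost = 0.3631
```

Reading the numbers: at `omega = (1, 1)` both communities saturate
(`rho_inf = 1`). At `omega = (0.6, 1)` the solver predicts global density
0.134 — the seeded community holds at 0.209 (its seeds, 0.2, plus a little
local adoption) and the other stays near zero — and an independent
simulation of an explicit 20,000-node network lands at 0.137. The abrupt
jump between those behaviors sits at `omega_intra ≈ 0.688`. For a strongly
modular network (`mu = 0.2`) the cheapest containing intervention keeps
the bridges fairly open (`omega_inter = 0.70`) while throttling
within-community spread hard (`omega_intra = 0.10`), at 36% of the maximal
regulation cost.

A command-line front end over the same functions is installed at
`inst/cli/regcascade.R`:

```sh
Rscript inst/cli/regcascade.R tl --z 15 --mu 0.5 --theta 0.25 --rho0 0.1 \
    --omega-intra 1 --omega-inter 1
Rscript inst/cli/regcascade.R optimize --z 20 --theta 0.1 --rho0 0.17 \
    --mu-grid 0.2,0.5,0.8
```

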