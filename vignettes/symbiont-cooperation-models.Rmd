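---
title: "Models of symbiont cooperation under mixed transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of symbiont cooperation under mixed transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcoop)
```

## The question

Vertically transmitted symbionts (passed from a host to its offspring) tend
to help their hosts more than horizontally transmitted ones (picked up from
the population at large). Two explanations are routinely offered. Under the
*transmission* hypothesis, vertical transmission itself aligns symbiont and
host interests: a symbiont whose descendants will live in its host's
offspring gains when the host has more offspring. Under the *relatedness*
hypothesis, vertical transmission matters only because it keeps the
symbionts sharing a host closely related, which favours cooperation among
them. `symcoop` implements a model family in which both forces operate and
can be separated: an analytical inclusive-fitness treatment in which
relatedness is first left free and then expressed through demography, and an
individual-based simulation of the identical life cycle that drops the
analytical approximations.

## Life cycle and fitness

Hosts form an effectively infinite, unstructured population with
non-overlapping generations; each carries a group of symbionts. A symbiont's
trait $x \in [0, 1)$ is the fraction of its resources spent on a service
that benefits only the host. Cooperation is individually costly: within a
host, a symbiont's share of the group's reproduction is
$(1 - x_i)/(1 - x_g)$, where $x_g$ is the host's mean trait. The host
benefits through survival and fecundity, as power laws $s(x_g) = x_g^s$ and
$f(x_g) = x_g^f$ with exponents $s, f \ge 0$ (the convention $0^0 = 1$ makes
an exponent of 0 mean "insensitive"). A new host is founded horizontally
with probability $\lambda$ and vertically otherwise. Horizontal founders
gain only from host survival; vertical founders gain from survival and from
fecundity. Relative to the population means this gives the focal-symbiont
fitness implemented in `symbiont_fitness()`:

$$
W \;=\; (1-\lambda)\,\frac{1-x_i}{1-x_g}\,
  \frac{x_g^s}{\bar{x}^s}\frac{x_g^f}{\bar{x}^f}
  \;+\; \lambda\,\frac{1-x_i}{1-x_g}\,\frac{x_g^s}{\bar{x}^s}.
$$

## The open model

A neighbour-modulated fitness analysis under weak selection gives the
selection gradient on cooperation in a monomorphic population
(`inclusive_fitness_effect()`):

$$
\Delta_{IF}(x) = -\frac{1}{1-x}
  + R\left[\frac{s + f(1-\lambda)}{x} + \frac{1}{1-x}\right],
$$

with $R$ the whole-group relatedness among the symbionts of a host
(including the focal symbiont itself). Solving $\Delta_{IF} = 0$ with
$A = f(1-\lambda) + s$ yields the candidate ESS

$$
x_0^* = \frac{RA}{RA + (1 - R)},
$$

returned by `ess_open()`. The slope of $\Delta_{IF}$ is negative at every
interior solution over $0 \le R, \lambda \le 1$, so these stationary points
are local fitness maxima; when no interior root exists ($R = 0$ or $A = 0$)
the gradient is negative throughout and the boundary $x^* = 0$ is reported.
Clonal symbionts ($R = 1$) cooperate fully. Because the algebra behind the
gradient is easy to get subtly wrong, the package carries a fully
independent check, `numeric_ess_oracle()`: the gradient is rebuilt from
central finite differences of `symbiont_fitness()` alone and its root found
by bisection; closed form and oracle agree to $10^{-6}$ across the test
grids.

```{r}
ess_open(open_params(R = 0.25, lambda = 0.5, s = 1, f = 2))
```

### Which matters more, relatedness or transmission?

The two marginal effects on the equilibrium,
$\partial x_0^*/\partial R = A/(R(A-1)+1)^2$ and
$\partial x_0^*/\partial \lambda = -fR(1-R)/(R(A-1)+1)^2$, share a
denominator, so transmission mode has the larger influence exactly when
$fR(1-R) > f(1-\lambda) + s$. `dominant_factor_open()` reports the winner
pointwise (with exact ties reported as `"tie"` rather than folded into a
label, since the boundary curve itself is of interest), and the searches
`dominance_lambda_infimum()` / `dominance_fs_infimum()` recover the region
boundaries numerically rather than from the algebra: an inner grid-seeded
maximization over $R$ and $f/s$, wrapped in an outer bisection. Transmission
mode can only dominate when transmission is mostly horizontal
($\lambda > 0.75$) and fecundity responds much faster than survival
($f > 4s$), and never at $R = 0$ or $R = 1$.

## Closing the model

Transmission mode also *determines* relatedness. If horizontally founded
hosts receive $k_h$ founders and vertically founded hosts $k_v$, whole-group
relatedness becomes (`whole_group_relatedness()`)

$$
R = \frac{k_h(1-\lambda) + \lambda k_v}{k_h\,(1 + (k_v - 1)\lambda)},
$$

which is 1 under full vertical transmission and $1/k_h$ under full
horizontal transmission. With equal bottlenecks $k_h = k_v = k$ this is
$R = 1/(1 + \lambda(k-1))$, and substitution into $x_0^*$ gives the
closed-model equilibrium (`ess_closed()`)

$$
x_c^* = \frac{A}{A + (k-1)\lambda}.
$$

The identity `ess_closed(p) == ess_open(R = whole_group_relatedness(p))`
is exact algebraically and is asserted to $10^{-12}$ on a thousand-cell
grid.

In the closed model a change in $\lambda$ acts through two routes:
directly, and via $R$. `route_decomposition()` returns the total derivative
$\partial x_c^*/\partial\lambda$, the direct part ($\partial
x_0^*/\partial\lambda$ evaluated at the demographic $R$), and their
difference, with the ratio $|indirect|/|direct| = A/(f\lambda)$. The
via-relatedness route wins everywhere except when $f > s$ *and*
$\lambda > 0.5$; `route_lambda_infimum()` recovers that boundary
numerically. When the direct route vanishes ($\lambda = 0$ or $f = 0$) the
ratio is reported as `Inf` rather than an error, because the full-vertical
limit is a meaningful regime.

## The individual-based simulation

`run_simulation()` implements the same life cycle with a finite host
population and explicit mutation, dropping the weak-selection and
monomorphism assumptions. Per generation: each host's $x_g$ sets its
survival weight $x_g^s$ and fecundity weight $x_g^f$; each of the $n$
offspring hosts is founded horizontally with probability $\lambda$
(founders drawn with replacement from the global pool, symbiont $i$ in host
$h$ weighted by $x_g(h)^s\,(1-x_i)/(1-x_g(h))$) or vertically (one parent
host drawn with weight $x_g^s x_g^f$, then $k$ founders drawn within it
with weight $1-x_i$); each founder mutates with probability $\mu$ by a
$\mathcal{N}(0, \sigma)$ step reflected into $[0, x_{\max}]$.

Design choices, made once and fixed:

* **Soft selection.** Host number is constant and selection acts through
  sampling weights, matching the relative-fitness ratios of the analytical
  model and avoiding demographic stochasticity in population size. Parents
  and founders are drawn with replacement (Wright–Fisher-style multinomial
  reproduction).
* **Vertical vs horizontal weights.** Within one parent host the
  $(1-x_g)$ denominator is a constant and cancels, so vertical founder
  weights are just $1-x_i$; across hosts it does not cancel, so horizontal
  pool weights keep the full $x_g^s(1-x_i)/(1-x_g)$.
* **Mutation kernel** defaults: $\mu = 0.01$ per founder,
  $\sigma = 0.02$ trait units, reflected at 0 and $x_{\max}$. Reflection
  preserves the domain without piling probability mass on an absorbing
  edge.
* **Trait clamp** $x_{\max} = 1 - 10^{-6}$: the within-host share and the
  horizontal weight are singular at 1, so the clonal prediction $x^* = 1$
  is approached, never attained, in simulation.
* **Initial condition** $x_{\mathrm{init}} = 0.5$ by default; convergence
  is start-independent (asserted for starts 0.1 and 0.9) so the choice is
  cosmetic.
* **Degenerate pools.** If every weight in a required pool is zero (all
  $x_g = 0$ with $s > 0$), sampling falls back to uniform with a warning
  instead of failing: the biological reading is that selection is then
  neutral among the (equally hopeless) candidates.
* **Burn-in.** Time averages exclude the first 25% of generations by
  default; the approach from the initial condition is clearly visible in
  trajectories.

Runs are bit-reproducible from `seed`. With 1,000 hosts and $k = 4$ a
2,500-generation run takes on the order of a second, so the package's
standard problem sizes (500–1,000 hosts, 1,500–3,000 generations, handfuls
of seeds) are comfortable on a laptop.

```{r}
sim <- run_simulation(sim_config(n_hosts = 200, k = 4, lambda = 1,
                                 n_generations = 400, record_every = 50,
                                 seed = 1))
sim
```

## Population statistics

**Realized relatedness.** `realized_relatedness()` is the regression form
of whole-group relatedness, $\mathrm{cov}(x_i, x_{g(i)})/\mathrm{var}(x_i)$
with the focal symbiont included in its own group mean, measured *at the
cooperation trait itself*. Measuring at the selected trait is deliberate:
it is what lets observed relatedness detach from the pedigree expectation
once cooperative and defecting lineages assort differently across hosts.
A neutral-marker mode (`track_tags = TRUE`, `marker_relatedness()`) carries
integer founder lineages through the same sampling and pools
allele-indicator covariances; it recovers $1/k$ under random horizontal
grouping and serves as the neutral control.

**Mode detection.** `detect_modes()` uses a Gaussian KDE (Silverman
bandwidth, floored at 0.005) and counts local maxima above 5% of the peak
density, merging adjacent maxima unless separated by a valley below 50% of
the lower one. The bandwidth floor is a genuine lower limit, not a free
constant: in the full-vertical regime the population is a set of discrete
clonal host lineages, and a markedly narrower kernel re-resolves that
granularity as spurious modes.

**Branching classification.** `classify_branching()` calls a run branched
only when at least two modes, each holding at least 5% of symbionts,
persist for at least `min_persistence = 5` consecutive recorded snapshots,
with the streak reaching the final half of the run. The persistence and
mass requirements are what keep transient mutation–selection polymorphism
(recurrent defector mutants under full vertical transmission and weak
bottlenecking) from being mis-called as branching; that regime is pinned by
a regression test. The constants are fixed and declared; the qualitative
branching map is insensitive to halving or raising the mass, valley and
peak-height constants, though calls in marginal mid-map cells (shallow,
slowly separating branches) can flip under a stricter valley rule — a known
limitation of any operational bimodality rule.

## What the simulations do and do not show

The simulator *is* the package's data generator: its defaults are the study
conditions, and every empirical statement in the package is computed from
it at run time. Non-branching runs recover the closed-model prediction
$x_c^*$: at interior equilibria the time-averaged mean trait lies within
three standard errors (across five seeds) of $x_c^*$ for six configurations
spanning $\lambda \in \{0.25, 0.75, 1\}$ and $k \in \{2, 4, 8\}$, using
500 hosts, 3,000 generations and averaging the final half (the transient
from $x_{\mathrm{init}} = 0.5$ decays over roughly the first thousand
generations at these sizes). Configurations whose predicted optimum lies on
the trait boundary ($\lambda = 0$, or $k = 1$, where $x_c^* = 1$) are
checked qualitatively instead: a reflecting boundary carries a systematic
mutation load of order $\mu\sigma$ relative deviation (simulated means
0.93–0.99 against a prediction of 1), which is a property of any
finite-mutation simulation rather than sampling error, so a standard-error
criterion is the wrong instrument there.

In monomorphic regimes the realized trait-based relatedness agrees with the
demographic prediction $1/(1+\lambda(k-1))$ to within $\pm 0.05$. Under
strong bottlenecking with intermediate horizontal transmission
(e.g. $\lambda = 0.25$, $k = 8$) the population reliably branches into a
cooperative cluster and near-zero "super-defectors", and branched runs show
observed relatedness *above* the pedigree prediction (by roughly +0.1 at
that cell) — the trait-relatedness feedback the analytical model excludes
by construction. None of this speaks to real symbiont systems directly: the
model has no host-side evolution, sanctions or partner choice, no
free-living symbiont stage, no host population structure, and only
power-law benefit functions.

## Sweeps and the command line

`run_sweep()` evaluates a factorial grid in one of five modes (`ess_open`,
`ess_closed`, `dominance`, `routes`, `simulate`) into a fixed-schema table;
failing cells become error rows rather than aborting the sweep, and
simulate-mode cells get deterministic per-cell seeds derived from a base
seed. `write_results()`/`read_results()` round-trip the table through CSV
or JSON. A thin command-line wrapper (`inst/cli/symcoop.R`, documented in
`?symcoop_cli`) exposes the same operations as shell subcommands with
JSON/YAML config files; it contains no logic of its own.

## Numerical conventions

* $0^0 = 1$ throughout (continuous limit of $x^s$ as $s \to 0$).
* ESS denominators are computed as $RA + (1-R)$ so the clonal limit
  $R = 1$ gives exactly 1 in floating point.
* Threshold searches bisect to $10^{-6}$ in $\lambda$ (relative $10^{-8}$
  in $f/s$) around grid-seeded inner maximizations; the $f/s$ range is
  capped at $10^4$.
* The finite-difference oracle uses step $10^{-6}$ and keeps $10^{-5}$
  away from the trait boundaries, where the fitness poles make finite
  differences unreliable.
* Exact marginal-effect ties are declared below a relative difference of
  $10^{-12}$.
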