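---
title: "Exploring transporter mechanism space: models, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring transporter mechanism space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportmc)
```

## The question the package answers

An alternating-access transporter with two conformations (outward-facing,
OF, and inward-facing, IF), one driving ion and one substrate already has
eight distinct occupancy states and twelve reversible transitions. Any
assignment of free energies to states and transition states defines a
thermodynamically valid kinetic model, and many qualitatively different
assignments perform the same function. `transportmc` treats the *model* as
the object of study: it enumerates the state space, solves each model's
steady state, and random-walks through model space under a fitness goal,
returning a trajectory of fully specified models rather than a single fit.

There is no experimental data in this workflow: the inputs are the machine
description and the environment, and every result is computed from
generated state spaces. This is the sense in which the package's own
fixtures (`build_fixture()`) and sampled ensembles "are" the data — they
emulate study conditions, not measurements.

## States, equivalence classes, and transitions

Raw states are strings `<CONF>-<code><o|b|i>-...` (e.g. `OF-Nb-Si`): each
species is outside, bound, or inside. With fixed bath concentrations on
both sides of the membrane, the location of an *unbound* particle is
physically irrelevant to the kinetics, so raw states sharing a conformation
and a bound/unbound pattern are collapsed into one class; class energies are
the sampler's parameters, and the master equation runs over classes. This
collapse reproduces the familiar 8-state diagram for the ion+substrate
machine and 12 classes when a mutually exclusive decoy is added (48 raw
states). Exclusion patterns (regular expressions on the raw string) can
remove states; occluded conformations are simply not declared by default
but may be added as extra conformations.

Only elementary transitions exist: one conformational change, or one
binding/unbinding event whose side is fixed by the conformation (strict
alternating access: OF exchanges with the outside bath, IF with the
inside). Every transition is reversible.

`enumerate_cycles()` brute-forces all simple directed cycles (a hard cap,
default $10^6$, guards against misuse — the intended spaces have at most a
few dozen classes, where exhaustive enumeration is exact and instant) and
reports each cycle's net transport per species, counted as bindings minus
unbindings on the outside face. On the 8-class space this recovers exactly
four minimal symport pathways of six transitions each, and the shortest
futile cycle of length four.

## Rates, driving, and thermodynamic consistency

Directed rates are Arrhenius-like, $\alpha_{ij} = k_0\,
e^{-(E^{bar}_{ij}-E_i)}$, with $E^{bar}_{ij}$ an *absolute* transition-state
level shared by both directions, so detailed balance at equilibrium is
built in. The prefactor $k_0$ (default $10^{-3}\,s^{-1}$) is a pure time
scale: all flows scale linearly with it and no ratio or mechanism depends
on it (a tested invariant).

Driving enters through the chemical-potential difference
$\Delta\mu_x = \ln([x_{in}]/[x_{out}])$ (k~B~T). A splitting factor
(default 1/2) distributes the driving across the two binding events of a
transport cycle:

* binding from outside: $\alpha \propto e^{-\,\mathrm{split}\,\Delta\mu_x}$
  (abundant outside $\Rightarrow$ fast binding),
* binding from inside: $\alpha \propto e^{+\,\mathrm{split}\,\Delta\mu_x}$,
* unbinding: no concentration factor.

A side-independent assignment (the same factor for binding regardless of
face) would cancel around every cycle and drive nothing; the side-dependent
form above is the minimal reading under which one transported particle
contributes exactly one $\Delta\mu_x$ of affinity per cycle. This is a real
design decision, isolated in one place (`rate_constant()` /
`.make_engine()`), and `cycle_affinity_check()` asserts the resulting
identity $\ln(\Pi\alpha_{fwd}/\Pi\alpha_{rev}) = -\sum_x n_x \Delta\mu_x$
on every simple cycle to $10^{-10}$.

## The decoy constraint (Hopfield-type discrimination)

A decoy is a weaker-binding copy of the substrate, destabilized by
$\Delta\Delta G$ in every bound state, mutually exclusive with it, and
otherwise kinetically identical — discrimination must come from the
affinity offset alone, never from species-specific barriers ("internal
proofreading").

Making that precise in an absolute-barrier formulation requires care. If
*every* decoy transition simply copied the substrate counterpart's absolute
barrier, all rates out of decoy-bound states would be uniformly faster by
$e^{\Delta\Delta G}$ and rates in would be unchanged. One can then check
(substituting $Q_i = P_i e^{\Delta\Delta G\, w_i}$, with $w_i$ the bound-decoy
indicator, into the master equation) that the transformed system is exactly
symmetric under swapping substrate and decoy, so by uniqueness of the
steady state the two species carry *identical* net flows on mirrored edges
— selectivity would be pinned at 1 for every model and every environment,
and no proofreading could exist. The package therefore ties barriers the
way Hopfield-type kinetics requires:

* the decoy's own binding/unbinding transitions carry the counterpart's
  absolute barrier — equal on-rates, off-rates faster by
  $e^{\Delta\Delta G}$;
* transitions *between two decoy-bound states* (conformational changes, ion
  binding while the decoy stays bound) carry the counterpart's barrier
  **plus** $\Delta\Delta G$ — the transition state still contains the
  destabilized decoy, so the barrier *height*, and hence the rate, matches
  the substrate branch.

Under this rule the equilibrium-limit selectivity of a leak-free
transporter is the binding-affinity factor $e^{\Delta\Delta G}$, driven
models can exceed it by paying ion-gradient free energy through a futile
leak cycle, and the decoy flux can stall or reverse at finite driving — the
phenomenology the sampler is meant to explore. All tied quantities are
derived parameters: trial moves perturb only free parameters and re-derive
the ties, so every sampled model satisfies the constraints exactly.

## The sampler

`explore_models()` is a Metropolis chain over the free energies:

* **Trial move** — one uniformly chosen free parameter (class energy or
  barrier) perturbed by $U(-s, +s)$ with step size $s = 1$ k~B~T; moves are
  symmetric, so no Hastings correction is needed.
* **Validity** — proposals violating $E^{bar} \ge \max(E_i, E_j)$ or the
  bounds (states in $[-10, 15]$, barriers in $[-5, 20]$ k~B~T; wide enough
  to contain all fixture mechanisms, narrow enough to keep rates
  representable) count as rejected steps, keeping the chain well defined.
* **Score** — the trial model's steady state is solved and its fitness
  $E_{MC}$ evaluated: $-J_{sub}$ (symport), $+J_{sub}$ (antiport), or
  $-J_{sub}(|J_{sub}|+\epsilon)/(|J_{dec}|+\epsilon)$ with
  $\epsilon = 10^{-15}$ (competitive).
* **Acceptance** — $p = \min[1, e^{-\beta \Delta E_{MC}}]$. Because fluxes
  carry the arbitrary $k_0$ scale, $E_{MC}$ is first divided by a reference
  flux $J_0 = k_0 e^{-5}$ (the rate over a typical 5 k~B~T barrier), making
  $\beta$ dimensionless.
* **Tempering** — the default schedule alternates $4\times10^4$ steps at
  $\beta = 10^5$ with $10^4$ steps at $\beta = 2$, cycled. The cold phase
  is deliberately near-greedy: the competitive score spans many orders of
  magnitude (from $\sim J_0$ down to $\sim J^2/\epsilon$), and a milder
  $\beta$ turns the chain into a free random walk long before fit models
  are reached. The hot phase accepts almost everything, acting as a partial
  re-randomization that lets a single run visit several fitness basins.
  These values were calibrated on acceptance-rate and best-so-far
  diagnostics for the 8- and 12-class machines; they are configuration, not
  science, and `mc_config()` exposes them.
* **Initialization** — class energies 0, barriers uniform in $[2, 8]$
  k~B~T: a valid, unfit, reproducible start.

Every `thin` steps (default 500) the current model is recorded with its
fitness and fluxes; identical configuration and seed reproduce the
trajectory bit for bit.

## Analysis and meta-analysis

`sweep_dmu()` re-solves the steady state along a grid of one species'
chemical potential (default ion, $[-8, 0]$ in 0.25 k~B~T steps, covering
the regimes of interest from strong driving to equilibrium);
`stoichiometry()` reports cost ($J_{ion}/J_{sub}$) and selectivity
($J_{sub}/J_{dec}$), with signed infinity markers at vanishing
denominators. `pathway_diagram()` scales net flows by the largest edge flow
and omits edges below $10^{-3}$ of it — negligible-flow arrows are not
drawn. `perturb_barrier()` applies targeted interventions;
`ion_only_edge()` selects the conformational transition between the
ion-only-bound states, the canonical futile-cycle ("ion leak") edge.

For model sets, `flow_vectors()` normalizes each model's net-flow vector to
unit Euclidean norm (removing $k_0$), `filter_models()` applies the
performance filter (substrate influx, cost above 0.1 — an upper bound such
as 10 can be supplied as well, both are exposed — and selectivity above
$10\,e^{\Delta\Delta G}$; a model whose decoy flux has vanished or
reversed passes the selectivity bound, since its discrimination is beyond
any finite ratio), and `cluster_models()` performs complete-linkage
clustering cut at distance 0.65, with medoids as deterministic cluster
representatives. `compare_runs()` gives nearest-neighbor distance
distributions between two runs.

## What the fixtures emulate — and what passing tests do not show

The four reference models are hand-built study conditions:
`ideal_symporter` (one minimal pathway open: low 3 k~B~T barriers on its
six edges, 15 k~B~T elsewhere, suppressing off-pathway flow by $e^{-12}$),
`mixed_symporter` (all four pathways open), `ideal_antiporter`, and
`hopfield_discriminator` — a 12-class model whose constants were tuned
numerically (by direct steady-state solves over a parameter scan) so that
at the operating condition ($\Delta\mu_{ion} = -4$,
$\Delta\mu_{sub} = \Delta\mu_{dec} = +2$, $\Delta\Delta G = 1$) the decoy
flux stalls near zero while the substrate is pumped in, the filter is
passed, and closing the ion-only edge collapses selectivity to about
$e^{\Delta\Delta G}$ (2.32 at these constants). The tuned values are frozen
constants in `R/fixtures.R`, not recomputed at load time.

These fixtures emulate idealized operating points of a coarse-grained
machine. They do not emulate real transporter data: there is no membrane
potential (charged-species electrostatics are out of scope), no occluded
intermediates, one binding site per species, and no transient kinetics —
the steady state is the only observable. Tests passing on these conditions
validate the algebra and the sampler, not any claim about a particular
protein.

A caution from our own sampling experiments: extreme optima of the
competitive fitness often discriminate through *several* futile-cycle
routes, including leaks that carry a bound substrate or decoy along. For
such models, closing only the ion-only edge removes part of the
dissipation, and the residual selectivity lands anywhere in
$[1, 2e^{\Delta\Delta G}]$ depending on the surviving leak structure
(values from about 1.5 to 3.7 across seeds in our runs). The clean collapse
to $\approx e^{\Delta\Delta G}$ is a property of models whose futile flow
is confined to the ion-only edge — the reference discriminator is one —
and the reproduction script uses that model for the leak-removal number
for exactly this reason.

## Numerical choices

* Steady state: dense linear solve with one balance row replaced by the
  normalization constraint; residual checked against $10^{-10}$ (relative
  to the largest exit rate). The spaces are tiny; robustness beats speed.
* Probabilities below $10^{-14}$ are clipped to zero and renormalized —
  barriers raised by 100 k~B~T produce rates of order $e^{-100}$ and the
  solver then returns harmless negative dust.
* Connectivity of the undirected transition graph is checked before
  solving (a disconnected graph has no unique stationary distribution and
  is reported as an ambiguity error).
* Canonical orderings everywhere: classes sorted by conformation then
  bound pattern, transitions lexicographic on (from, to) — flow vectors are
  comparable across runs by construction.
* Cycle enumeration anchors each cycle at its smallest class id, so each
  directed cycle is produced exactly once; a cycle and its reversal are
  distinct (opposite net transport).
* Problem sizes in the tests and the reproduction script: $10^5$ MC steps
  for the symport/antiport discovery runs and $2\times10^5$ for the
  competitive filter demonstration — the discovered optima are already
  converged to the 1:1 flux ratio at well below 1% there, so longer
  default runs ($10^6$) are reserved for actual exploration work.

## Known limitations

* The side-sign convention for the chemical-potential factor is a modeling
  choice; any convention assigning one $\Delta\mu_x$ per transported
  particle per cycle gives the same cycle affinities but may distribute
  rates differently along a pathway. It is configurable only through the
  splitting factor, not per side.
* The decoy tie rule is the package's resolution of a genuinely
  underdetermined constraint (see above); alternative resolutions exist
  but either forbid discrimination altogether or introduce internal
  proofreading.
* Complete-linkage clustering at a fixed 0.65 cut is descriptive, not
  model-selected; the threshold is exposed and no automatic choice is
  attempted.
* The Metropolis ensemble is not a Boltzmann ensemble over models; β is a
  search parameter, and all quantitative claims rest on the recorded
  models' steady states, not on sampling weights.
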