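---
title: "Modeling retroactivity-driven off-target effects of targeted inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling retroactivity-driven off-target effects of targeted inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrokin)
```

## The question

Signaling cascades are usually drawn with information flowing one way: an
upstream kinase activates a downstream substrate. But the biochemistry is
bidirectional. A downstream substrate *consumes* its upstream kinase by
binding it, so perturbing the downstream cycle changes how much free kinase
is available to everything else that kinase activates. This upstream
propagation of a downstream perturbation — *retroactivity* — requires no
feedback loop, only mass conservation.

`retrokin` asks a pharmacologically pointed version of the question: if a
competitive inhibitor sequesters the active protein of one covalent
modification cycle, can the steady state of a *different, non-targeted*
cascade shift by a detectable amount, purely through this sequestration
chain? And over what fraction of kinetically plausible parameter space?

## The model

Each cycle `i` interconverts an inactive protein `Y_i` and its active form
`Y_i*` through a kinase reaction and a phosphatase reaction, both modeled
by elementary mass action:

    Y_i + Ek_i  <-> C_i   -> Y_i* + Ek_i      (a_i, d_i, k_i)
    Y_i* + Ep_i <-> C'_i  -> Y_i  + Ep_i      (a'_i, d'_i, k'_i)
    Y_n* + D    <-> C_D                       (kon, koff)

Cycle 1 has a dedicated kinase; its product `Y1*` is the shared activator
of the other cascades. The drug `D` binds the targeted active species
reversibly and does nothing else — it carries no catalysis and does not
change the phosphatase's rate constants. Three motifs are supported:
*vertical* (the targeted cascade is a chain of cycles 3, 4, ..., n),
*lateral* (cycles 2..n fan out in parallel from `Y1*`), and *extended*
(the three-cycle network plus a cycle 4 activated by `Y2*`, for studying
downstream amplification). Cycle 2 is always the monitored, non-targeted
reporter, in a different cascade from the targeted cycle.

At steady state every complex can be eliminated exactly through its own
balance equation, which collapses the network to `2n` equations in the
normalized free concentrations `y_i = [Y_i]/YT_i` and
`y_i* = [Y_i*]/YT_i`, governed by five dimensionless parameters per cycle
plus one drug constant:

| parameter | meaning | default sampling range |
|---|---|---|
| `E_i`  | total kinase : total substrate | 0.01 – 100 |
| `E'_i` | total phosphatase : total substrate | 0.01 – 100 |
| `K_i`  | kinase `Km` / substrate total | 0.01 – 100 |
| `K'_i` | phosphatase `Km` / substrate total | 0.01 – 100 |
| `P_i`  | kinase `Vmax` / phosphatase `Vmax` | 0.1 – 10 |
| `K_B`  | drug `Kd` / targeted substrate total | 0.01 – 100 |

`K_i < 1` means the reaction runs at substrate saturation (zero-order
regime) — the regime in which sequestration is strong; `K_i > 1` is the
linear regime. `P_i > 1` biases a cycle toward its active form. The drug
enters only through its normalized total `I = DT / YT_n`.

The off-target protocol solves the steady state at `I = 1e-4`
(operationally "no drug": results are indistinguishable from `I = 0`) and
`I = 1e4` (saturating), and reports an off-target effect in a monitored
cycle when either free species there changes by at least 0.10 of that
cycle's total protein. The threshold is inclusive, and the effect size of
a cycle is `max(|Δy|, |Δy*|)`. The deliberately huge dose range makes the
two-endpoint shortcut safe; in practice most of the transition happens
between `I = 0.1` and `I = 10`, which `stimulus_response_curve()` shows
directly.

```{r worked-example}
spec <- build_network("vertical", 3)
compute_response(get_parameter_set("random_set"), spec)
```

## Solving the steady state

Two independent routes are implemented, and agreement between them is part
of the test suite.

**Algebraic route** (`solve_steady_state_algebraic()`, the fast path).
The supported topologies decompose into simple chains hanging off cycle 1.
Within a chain, guessing the *bottom* cycle's activity lets conservation
and rate balance be swept upward in closed form, yielding the activator
concentration the chain demands at its top; a bracketed bisection on the
bottom activity matches that demand to the supplied activator. Cycle 1 is
then itself bisected on `y1*` against its conservation equation, with all
chains re-solved per trial. Because every scalar solve is a bisection of a
bracketed root on `[0, 1]`, the method has no divergence failure modes and
runs to machine precision in about 90 iterations per level (~2 ms per
steady state for the three-cycle network). Every solution is verified
against the full residual system; anything above `1e-6` falls back to
integration.

**Integration route** (`integrate_to_steady_state()`). The dimensionless
set is mapped to a dimensional realization, the full ODE system (including
all complexes) is integrated with `deSolve::lsoda` from the resting state
— all substrate unphosphorylated and free, enzymes free, no complexes,
free drug at its total — and the endpoint is verified against the same
algebraic residuals. The resting start is the natural experimental
convention (drug applied to an unstimulated system); uniqueness of the
reached state is additionally probed by the cross-method agreement tests,
which compare a root found by bisection from above with a trajectory
arriving from a completely different direction. In the explorations run
for this package the two methods have never disagreed beyond `1e-6`.

Integration tolerances default to `rtol = 1e-10` and a pool-scaled
`atol = 1e-12` — tighter than typical, because residual terms like `y/K`
amplify integration error by up to `1/K = 100` at the bottom of the `K`
ranges, and the verification step demands residuals below `1e-6`.
Integration stops at the first checkpoint where the residual verifies and
normalized rates have fallen below `1e-9`, and errors out (carrying the
residual) if `t_max = 1e5` arbitrary time units is exhausted; batch
explorations count such sets as excluded non-effects and report the count
(in the default spaces, exclusions have not occurred).

**The dimensional mapping is arbitrary, and provably irrelevant.** The
dimensionless steady state fixes a dimensional realization only up to a
concentration scale (`YT_1 = 1`), a timescale (`k'_i = 1`), and the split
of each Michaelis constant `(d + k)/a` (we tie `d = k`). The test suite
solves the same sets under different scale choices and checks agreement to
`1e-8`, which is why trajectories are reported in arbitrary time units
while steady states are exact.

## Exploring parameter space

`lhs_sample()` draws Latin hypercube samples with per-parameter
stratification *on the log10 scale*: sampling a decade-spanning biochemical
ratio uniformly on a linear scale would place 99% of draws in the top two
decades, and the decade sub-range structure of the perturbation analysis
presumes all decades are populated evenly. Log-uniform sampling is also
internally consistent: the full-space off-target percentage matches the
equal-weight average of the per-decade percentages (a property the test
suite checks), which cannot hold under linear-uniform sampling.
Linear-scale ranges remain available via `parameter_range(scale =
"linear")` for sensitivity checks.

`explore()` runs the two-endpoint protocol over a batch (5000 sets by
default, the size at which the detected percentage stabilizes) and reports
per-cycle off-target percentages and an effect-size histogram in bins
`[0.1, 0.2), ..., [0.9, 1.0]`.

`make_plan()` + `run_perturbation()` implement the decade sub-range
sensitivity method: one parameter at a time is restricted to a single
decade of its default range while everything else samples the full space,
and the shift in the off-target percentage relative to baseline measures
that parameter's leverage. For the three-cycle network this is 59 runs
(13 four-decade parameters, 3 two-decade `P` parameters, 1 baseline); the
sub-ranges are half-open `[lo, hi)` except the final decade (the published
decade lists overlap at their endpoints, so some convention is required;
with continuous sampling the choice affects nothing measurable). Each run
draws a fresh, independently seeded sample — reusing one stream across
runs would correlate the "all other parameters" draws between runs — and
its seed is recorded in the report.

`restriction_rules_default()` ships a reconstruction of the
high-probability restricted space implied by the perturbation results:
cycle 3 saturated and deactivation-leaning (`K3, K'3` in `[0.01, 0.1]`,
`E3, E'3` in `[0.01, 1]`, `P3` in `[0.1, 1]`), cycle 1 activation-leaning
with an efficient kinase (`K1` in `[0.01, 0.1]`, `K'1` in `[10, 100]`,
`P1` in `[1, 10]`), and cycle 2's kinase reaction in the linear regime
(`K2` in `[1, 10]`). The exact ranges used for the published restricted
space are not available, so these decades were chosen once from the
perturbation analysis's strongest effects; under them roughly 85% of
sampled sets produce a cycle-2 off-target effect (versus ~1.6% in the
full space), and the percentage decays with network size in the vertical
case and faster in the lateral case, as expected. Tests of this space are
deliberately qualitative (far above baseline; non-increasing in `n`)
rather than numeric reproductions.

## Fixtures

Two parameter sets ship with the package (also as YAML under
`inst/extdata/`). `"random_set"` is a randomly drawn set with a large
off-target response, useful as a worked example. `"xenopus_set"` derives
from the classic Huang & Ferrell (1996) *Xenopus* oocyte MAPK cascade
model: concentration totals give the `E` ratios, shared Michaelis
constants of ~300 nM give the `K` values, and equal catalytic constants
reduce each `Vmax` ratio to a ratio of enzyme totals — in particular
`P2 = 3 nM / 0.3 nM = 10` and `P3 = 3 nM / 120 nM = 0.025`. Note that
several of its enzyme : substrate ratios (2.5e-3, 2.5e-4) fall *below*
the default sampling ranges; the set is deliberately kept valid, a
reminder that the default space is conservative about physiological
extremes.

## Study sizes and runtime choices

Batch explorations default to 5000 sets; the acceptance workflow runs each
headline exploration at that size (10,000 steady-state solves per
exploration, under a minute each on one CPU via the algebraic path). The
cross-method agreement test uses 100 LHS sets, mapping invariance 20 sets,
and the network-size scaling comparison 2000 sets per size — sizes at
which binomial sampling error is small relative to the effects being
checked.

## What the generator does and does not emulate

The sampled spaces emulate *kinetic plausibility*, not any measured
parameter distribution: independent log-uniform draws over broad ratio
ranges, with cycles beyond the third tied to cycle 3's values in larger
networks to keep the sampled dimension at 16. Real signaling proteins have
correlated kinetics, expression far from independent across a cascade, and
regulation (synthesis, degradation, scaffolding, feedback) that this model
deliberately omits so that sequestration is the *only* coupling mechanism.
A passing test suite therefore demonstrates that retroactivity alone can
produce detectable off-target effects under plausible kinetics — not that
it will do so in any particular pathway. Oscillatory and multistable
regimes are out of scope (no disagreement between the solver's independent
routes has been observed in the sampled spaces, but the solver reports,
rather than hides, any such disagreement via its verification step).

## Known limitations

* Steady-state only: transient excursions, which may matter *in vivo*, are
  computable from `build_ode_system()` but no transient statistics are
  defined.
* The restricted-space results are reconstructions; their percentages are
  order-of-magnitude comparable to, but not numerically identical with,
  the published ones.
* Topologies are limited to chains hanging off a single shared activator;
  arbitrary DAGs of kinase assignments would require generalizing the
  chain-shooting solver.
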