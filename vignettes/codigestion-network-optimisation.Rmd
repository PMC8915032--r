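---
title: "Optimising a centralised anaerobic co-digestion network"
author: "ancdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimising a centralised anaerobic co-digestion network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancdnet)
```

## The problem

A river-basin sanitation system contains many producers of organic
waste — wastewater treatment plants (WWTPs) whose sludge is not digested
on site, and agro-industrial substrate generators — and a few WWTPs
whose anaerobic digesters have spare capacity. Routing the right
substrate volumes to the right digesters turns a disposal problem into
biogas, but the blend fed to each digester must stay biochemically
safe, and hauling sludge across a basin has a real logistic cost. The
package plans this allocation.

Formally, the network is a complete bipartite graph between `W`
generators and `R` receptors. Each generator `w` produces `V_w` L/day
with a fixed characterisation (COD, COD/TN ratio, alkalinity, lead
concentration as the toxicity proxy). The shipped volume on each edge
`(w, r)` is discretised: it must be one of
`0, q, 2q, ..., floor(V_w/q)*q`, plus `V_w` itself when `V_w` is not a
multiple of the quantum `q` (default 1000 L), so full utilisation stays
representable. A generator may split its volume across receptors
(configurable to single-receptor assignment), but never ship more than
it produces. The result is a multidimensional-knapsack-type problem:
NP-hard, with a search space that grows multiplicatively per edge.

## Objective and constraints

Every generator carries four dimensionless quality coefficients:
`f1` (biogas potential from COD), `f2` (COD/TN adequacy), `f3`
(alkalinity adequacy) and `t` (toxicity). The cost index of an
allocation is

    B' = K * sum over edges (v_wr / V_w) * t_w *
         combine( (f1 + f2 + f3)^rho_q , rho_x * X_w * d_wr * I_w )

with `K = +1` or `-1` a solver sign convention (all comparisons use
`B = |B'|`), `rho_q = rho_x = 0.5` balancing quality against logistics,
`X_w` a transport cost rate (currency/km), `d_wr` the road distance and
`I_w` a 1–3 social impact score. Two genuinely open readings are kept
as switches:

* **Quality weighting.** The quality term is written with `rho_q` in
  superscript position, so the default raises the coefficient sum to
  the power 0.5 (`quality_weight_mode = "exponent"`); a plain
  multiplier mode is available.
* **Logistics sign.** Written literally, the index *adds* the
  logistics term, which would reward long hauls — yet in the study a
  tenfold distance increase collapses the attainable index towards
  zero, which only makes sense if distance is penalised. The default
  (`logistics_mode = "penalty"`) therefore subtracts the
  max-normalised logistics term from the quality term and clamps at
  zero; the literal additive form is retained as an option.

Feasibility `g(x)` is evaluated per receptor on the volume-weighted
blend of everything it accepts: external intake at most the receptor's
acceptable volume; blend COD/TN within [20, 60] (below, acidification
and ammonia inhibition risk; above, nitrogen starvation); blend
alkalinity within [2500, 6000] mg CaCO3/L (pH buffering); blend lead
at most 2.1 mg/L. Bounds are inclusive. TN is derived per source as
COD/(C/N) *before* mixing, so the blend C/N is a ratio of summed masses,
never an average of ratios — this is what makes the blend C/N obey the
mediant bounds of its constituents, a property the tests exercise.

Biogas is estimated at 0.268 m3 per kg of COD fed. Organic loading
rates are reported per m3 of digester working volume; where a digester
volume is not recorded, it is approximated as a 20-day hydraulic
retention time times the receptor's acceptable intake, and flagged as
derived.

### Coefficient forms

The exact published equations for `f1, f2, f3, t` live in a figure
whose panels are not machine-readable in our source material, so the
shipped default uses transparent stand-in forms with the documented
qualitative behaviour: `f1 = COD / COD_ref` (reference = the network
maximum, so the richest substrate scores 1); `f2` and `f3` are
trapezoidal memberships equal to 1 on the operating windows with linear
shoulders (default width: half the plateau); `t = max(0, 1 -
tox/tox_max)`, so a substrate at or above the lead ceiling contributes
nothing. `coefficient_mode = "figure2"` accepts user-transcribed
equation functions and refuses to run without them. No claim is made
that the fallback forms reproduce the published coefficient values;
all package results should be read under this caveat.

## Solvers

Three stochastic solvers share one evaluation contract and one
campaign harness (population 100, 500 iterations, best of 10
repetitions by default — the study's settings, with ACO `alpha = 1,
beta = 2, rho = 0.98`, GA crossover 0.8 and 5% elitism, PSO cognitive
0.8 and social 1.25).

**Constraint handling.** The penalty contract is the *death penalty*
by default (infeasible fitness 0; a linear violation penalty is
available). Implementation showed the bare death penalty leaves the
baseline landscape flat: random allocations are essentially never
feasible, because the blend C/N corridor [20, 60] requires a balanced
industrial fraction — pure sludge blends sit below 20, and industrial
substrates are so COD-rich that unconstrained mixes overshoot 60 by an
order of magnitude. All solver-internal *comparisons* therefore use
constraint dominance (Deb's rules): any feasible solution outranks any
infeasible one, and infeasible solutions are ranked by their summed
normalised violation magnitude. Reported fitness values follow the
penalty contract unchanged. This is the single most consequential
design choice in the package; without it none of the three solvers
finds a nonzero feasible baseline solution.

* **ACO (max-min ant system).** Ants construct an allocation edge by
  edge, picking option `s` with probability proportional to
  `tau^alpha * eta^beta`. Construction is capacity-masked, as is usual
  for knapsack ACO: only options within the receptor's remaining
  intake and the generator's remaining volume are admissible, so
  constructed solutions always satisfy the volume constraints.
  `eta` is the option's marginal cost-index term; the zero option is
  given the edge's *median nonzero* `eta`, because a vanishing floor
  would make exclusion unreachable at `beta = 2` (selection odds of
  order 1e-12) and the C/N corridor demands learnable exclusion.
  Trails evaporate by `rho` per iteration; the iteration-best feasible
  ant deposits (normalised by the best fitness so far), or, while no
  feasible ant exists, the least-violating ant deposits at half
  strength; trails are clamped to `[tau_min, tau_max]`
  (defaults 0.001 and 1).
* **GA.** Integer chromosomes of option indices; tournament selection
  (size 2; rank selection available) under constraint dominance;
  uniform crossover on the configured fraction of non-elite offspring;
  per-gene mutation at rate 1/E; elites copied unchanged.
* **PSO.** Particles move in the unit cube, one coordinate per edge,
  decoded to the nearest option for evaluation; standard velocity
  update with inertia interpolated 0.9 to 0.4 and velocities clamped
  to 20% of the range; personal/global bests compared by constraint
  dominance.

Tie-breaks everywhere are first-encountered-wins at equal fitness.
Campaign repetition `r` uses seed `seed + r - 1`, so campaigns are
reproducible while repetitions stay independent; identical seed and
configuration give bit-identical results.

An exhaustive oracle (`brute_force_oracle()`) enumerates every option
combination on small instances (refusing beyond a combination cap) and
anchors the solver tests: on screened tiny instances all three solvers
reach the oracle optimum exactly.

Note one structural fact: the empty allocation is always feasible
(an idle receptor violates nothing), so a campaign can always return a
feasible — possibly zero-value — plan; `feasible_found = FALSE` can
only occur if not even the empty allocation is ever sampled.

## Synthetic networks and what they do (not) show

`generate_network()` draws instances inside the empirical envelopes of
the bundled case data: sludge COD 16,900–23,400 mg/L, C/N 14–21,
alkalinity 1,800–10,100 mg/L, volumes 4,400–47,000 L/day; industrial
COD 155,900–667,400 mg/L and C/N 32–33,000 drawn log-uniformly (their
empirical ranges span orders of magnitude), alkalinity 20–660 mg/L,
volume 9,000 L/day; toxicity 0.01–2.30 mg Pb/L; distances 5–67 km.
Receptor capacities are drawn so the total generator volume is 1–4
times the total capacity — instances are non-trivially constrained.
The generator emulates marginal ranges only: it does not reproduce
spatial correlation between distance columns, seasonal variation of
volumes, or correlated characterisation (e.g. high-COD sources tending
to low alkalinity appear only through the per-kind envelopes). Passing
tests on synthetic instances therefore certify algorithmic behaviour,
not predictions about any particular real basin.

For solver-versus-oracle testing, instances are screened — by the
oracle alone, never the solvers — to have a *positive* exhaustive
optimum, because unscreened tiny instances are usually degenerate (the
C/N corridor admits only the empty allocation, and a comparison of
zeros certifies nothing). The test suite uses 20 such instances: 10
single-receptor (2 sludge + 1 industrial, quantum 20,000 L) and 10
two-receptor (quantum 30,000 L), all under 1,000 combinations.

## Numerical choices

* Feasibility bounds are inclusive, with a relative tolerance of 1e-9
  so boundary blends (e.g. C/N exactly 60) pass deterministically.
* Allocation option membership is checked to 1e-9 relative tolerance.
* The zero-volume blend is flagged undefined rather than given
  concentrations; averages across receptors are volume-weighted over
  receptors with intake.
* The ACO admissibility cutoff uses `findInterval` with an absolute
  1e-9 slack so an exactly-fitting option remains admissible.
* Evaluation is batched: the cost index is linear in the allocated
  volumes and every per-receptor and per-source aggregate is a single
  matrix product, which is what makes 100 x 500 x 10 campaigns take
  seconds in pure R (baseline: GA/PSO about 10 s, ACO about 40 s on
  one CPU; the oracle-equivalence battery of 60 campaigns runs in
  about 2.5 minutes).

## Known limitations

* The published case study's headline index values, biogas totals and
  organic loads are *not* reproducible from printed inputs alone: the
  transport cost rates `X_w`, social impacts `I_w`, receptor base
  sludge streams and digester volumes, and the exact coefficient
  equations are not public. Defaults (`X_w = 1`, `I_w = 1`, no base
  stream, HRT-derived digester volumes, fallback coefficients) keep
  every term well-defined and overridable, and the package's checks are
  property-based (bounds re-verification, oracle equivalence, exact
  scenario transforms) rather than value reproduction.
* Blend constraints are evaluated on external substrates only by
  default, because receptor base-stream volumes are unknown;
  `mixing = "with_base"` folds in the receptor's own stream when a
  base feed volume is supplied.
* Whether the original study allowed volume splitting across receptors
  is unstated; the per-edge model is the more general reading and
  `single_receptor = TRUE` restores single-assignment.
* No reactor kinetics: coefficients are static per-substrate values,
  so the model ranks blends, it does not simulate digestion dynamics.
* Truck logistics assume constant density (default 1 kg/L), full loads
  and a fixed route per edge; no routing, daytime scheduling or stock
  dynamics.

## A worked example

```{r example, eval = FALSE}
net <- besos_network()
net

cam <- ancd_solve(net, "ga", seed = 1)   # pop 100 x 500 iters x 10 reps
cam
ev <- evaluate_allocation(coef(cam), net)
performance_summary(ev, net)
blending_profile_report(coef(cam), net)
logistics_schedule(coef(cam), net)

# stress scenarios, e.g. tenfold COD:
s1 <- apply_scenario(net, standard_scenarios()$S1)
run_benchmark(net, standard_scenarios()["S2b"], algorithms = "pso",
              cfg = solver_config("pso", repetitions = 3, seed = 1))
```

The chunk is not evaluated while building the vignette (a full campaign
takes seconds to minutes); the README shows a complete run with its
actual printed output.
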