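---
title: "gutsim: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutsim: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsim)
```

## The model

`gutsim` is a discrete-time, stochastic agent-based model of four bacterial
genera -- *Bifidobacterium*, *Bacteroides*, *Clostridium* and
*Desulfovibrio* -- competing for carbohydrate metabolites on the wall of the
ileum. The wall is discretized into a 1 x 100 lattice of elements; one
timestep represents 26.3 s of real time, so 10,000 steps are roughly three
days. Each agent is a *colony* standing for an equal, unspecified number of
bacteria. A colony carries a genus, an energy level in [0, 100], a
continuous axial position `x` in [0, 100) (its element is `floor(x)`), and
an adhesion state: `FREE` in the lumen, `MUCUS` (bound to the mucus layer),
or `SEED` (permanently embedded in mucus or crypts).

Metabolites are environmental variables, not agents: a per-element,
per-metabolite field of units. Six slots are configured -- glucose, lactose,
fructooligosaccharide, inulin, lactate, and an unassigned spare slot with no
inflow and no consumers, kept so that an additional metabolite can be wired
in purely through configuration.

The metabolic web is deliberately small: *Bifidobacterium* consumes glucose,
lactose, fructooligosaccharide and inulin and deposits lactate on its
element when it feeds; *Desulfovibrio* consumes only that lactate;
*Clostridium* and *Bacteroides* are configured identically and consume only
glucose -- the pair differs only in initial abundance, which makes them a
useful internal probe of how initial conditions propagate. All interaction
between genera is indirect, through competition for these shared resources;
there are no direct bacteria-bacteria interactions.

Model assumptions, encoded as fixed contracts of the engine:

* unidirectional, constant-velocity flow; free colonies advect by a fixed
  displacement per step (default 0.278 elements) and are removed when they
  pass the distal end (*washout*);
* no self-motility or diffusion -- bacterial self-propulsion is about 5% of
  the lateral flow speed (`ileum_physiology()`), so advection dominates;
* constant, genus-wise-identical doubling times;
* colonies depend exclusively on the metabolites simulated in the model.

## Per-step update rules

Each timestep applies, in a fixed order that is a documented constant of
the engine:

1. **Boundary inflow.** Each metabolite's `inflow_per_step` units are added
   to the entrance element; per-genus colony inflow (see *Composition
   anchoring* below) and any probiotic dose enter at the entrance with full
   energy, `FREE`.
2. **Adhesion.** A free colony sticks to the mucus layer with probability
   $\gamma = \gamma_{max}\!\left[1 - \frac{N}{N_{mid}+N}\right]$, where $N$
   is the colony count on its element: adhesion saturates with local
   crowding, halving at $N = N_{mid}$. A mucus-bound colony becomes
   permanently embedded (`SEED`) with probability 0.05, otherwise escapes
   back to the lumen with probability 0.10. Seeds never change state.
3. **Advection.** Free colonies move downstream by the displacement;
   colonies past element 99 are washed out. Metabolites advect with the
   same displacement as a deterministic fractional transfer: a fraction
   `min(1, displacement)` of each element's units moves one element
   downstream, and units leaving the last element are lost. A config flag
   (`flow$advect_metabolites`) pins the field in place for sensitivity
   analyses.
4. **Consumption and energy.** A colony is *hungry* when its energy is
   strictly below 80. On each element, metabolites are visited in a fixed
   priority order (glucose, lactose, fructooligosaccharide, inulin,
   lactate); for a metabolite with `U` whole units and `H` hungry eligible
   colonies, every hungry colony eats one unit if `H <= U`, otherwise `U`
   winners are drawn uniformly without replacement. A colony consumes at
   most one unit of one metabolite per step. Each consumer gains 20 energy
   (capped at 100) and deposits its production yields; every colony then
   loses `100/1440` energy, so a full-energy colony survives exactly 1440
   steps without food. Colonies at zero energy are removed.
5. **Reproduction.** At timesteps that are multiples of the genus' doubling
   time (480 steps, about 3.5 h), each colony with strictly more than 50
   energy on an element below the occupancy cap (200) spawns a daughter at
   its position. Parent and daughter split the parent's energy evenly; the
   daughter is released from the mucosal layer (`FREE`), the parent keeps
   its adhesion state.

The ordering is chosen so that a probiotic dose injected at the inlet
advects and can feed within its arrival step. Reproduction is evaluated
against the completed-step index (`t + 1`): the alternative (the pre-step
counter) would trigger a full population doubling on the very first step
after seeding, since every seeded colony starts at full energy and `0` is a
multiple of every doubling time.

## Parameters

| Parameter | Default | Units | Provenance |
|---|---|---|---|
| `n_elements` | 100 | elements | reference geometry |
| `flow$displacement_per_step` | 0.278 | elements/step | reference value (healthy residence time) |
| `flow$timestep_seconds` | 26.3 | s | reference value |
| `energy$starvation_steps` | 1440 | steps | reference value |
| `energy$hungry_threshold` | 80 | energy | reference value |
| `energy$reproduce_min_energy` | 50 | energy | reference value |
| `adhesion$p_unstick` | 0.10 | prob/step | reference value |
| `adhesion$p_embed` | 0.05 | prob/step | reference value |
| glucose inflow | 30 (60 / 15 perturbed) | units/step | reference value |
| doubling time | 480 | steps | ~3.5 h, equal across genera |
| seeding | 78.43 / 18.27 / 3.06 / 0.23 | % | reference composition |
| `initial_total` | 10,000 | colonies | chosen so the percentages land on integers |
| `max_per_element` | 200 | colonies | space constraint, unpublished |
| `adhesion$gamma_max` | 0.01 | prob/step | calibrated (see below) |
| `adhesion$n_mid` | 30 | colonies | calibration knob |
| `energy$gain_per_unit` | 20 | energy/unit | one meal offsets ~288 steps of decay |
| secondary carb inflows | 4 each | units/step | calibrated |
| lactate yield | 0.01 | units/unit consumed | calibrated (see below) |
| bacterial inlet flux | 0.7843 / 0.1827 / 0.0306 / 0 | colonies/step | calibrated, proportional to seeding |

## Calibration protocol

Several parameters of the original experimental design were never
published: the adhesion ceiling `gamma_max` and midpoint `n_mid`, the
energy gain per unit, the inflows of the secondary carbohydrates, the
lactate yield, and the baseline bacterial inlet flux. These are calibration
knobs. They were fixed once, against two qualitative properties of the
system being modeled -- not against any numeric target:

1. **Baseline stability.** Seeded with the reference composition, a control
   run must hold an approximate steady state near that composition for
   30,000 steps. This rules out large `gamma_max` (0.1 and above): strong
   adhesion funnels the entire population into the absorbing `SEED` state
   within days, making the community insensitive to flow -- flow-rate
   perturbations are a central part of the experimental design, so that
   regime is wrong. It also rules out large lactate yields (0.1 and above),
   under which *Desulfovibrio*, seeded at 23 colonies, grows two orders of
   magnitude; lactate production is deliberately low in this web.
2. **Transience of perturbations.** Populations should return toward
   control after a perturbation ends. Pure neutral competition has no
   restoring force for genus composition, so the fixed-flux boundary
   condition carries a small bacterial inlet flux *proportional to the
   seeded composition* (fractional colonies per step, emitted through an
   accumulator). Proportionality matters: any disproportionate inflow acts
   as a per-genus energy subsidy that exponentially suppresses the
   under-supplied genera. *Desulfovibrio*'s proportional share (0.0023
   colonies/step) is truncated to zero, because any nonzero immigrant
   stream would make its complete die-off under strong washout -- a
   documented model behavior -- formally impossible.

With the frozen values (`gamma_max = 0.01`, `n_mid = 30`, yield 0.01,
secondary carbs 4 units/step, inlet flux ~1 colony/step) a control run
settles near 80/16/3/0.3% with *Desulfovibrio* at a few tens of colonies.

The strength of the inlet anchor trades off two published behaviors: a
stronger anchor (about 5 colonies/step) makes every perturbation fully
transient but erases *Desulfovibrio*'s dominant response to a high-glucose
diet and the mid-gut spatial aggregation under slow flow; the weaker anchor
preserves both at the cost of incomplete recovery (residuals of 5-12
percentage points) for the two minor glucose consumers after a
perturbation. The package ships the weaker anchor, because the
lactate-driven *Desulfovibrio* response and the spatial aggregation are the
model's most distinctive predictions; the incomplete minor-genus recovery
is flagged as a known limitation below, and the corresponding acceptance
checks are left failing rather than weakened.

## Numerical choices

* The metabolite field is a continuous (double) array; consumption happens
  in whole units (`U = floor(units)`), so fractional production (lactate at
  0.01/meal) accumulates invisibly until a whole unit is available. Books
  balance to 1e-9 per step, verified on every step of the conservation
  suite.
* Starvation death uses `energy <= 1e-9` rather than `== 0` so that the
  1440-step survival statement is exact under floating-point decay
  accumulation; the death step of a non-eating colony with energy `E` is
  exactly `ceiling(E / decay)`.
* Reproduction and consumption thresholds are strict inequalities
  (`energy > 50`, `energy < 80`), matching the stated boundary behavior
  (a colony at exactly 50 does not reproduce; at exactly 80 it does not
  eat).
* All stochastic draws flow through R's RNG (also inside the C++ engine),
  so `set.seed()` -- or the `rng_seed` / `seed` arguments -- makes entire
  trajectories bit-reproducible; replicate `i` of an ensemble uses
  `base_seed + i`. Composing the exported single-step operations yields
  exactly the same trajectory as the compiled multi-step loop.
* Ties in oversubscribed consumption are broken by a partial Fisher-Yates
  shuffle (uniform subsets without replacement).

## Scenarios and statistics

`run_scenario()` realizes the three-phase protocol -- baseline,
perturbation, recovery, 10,000 steps each by default -- for seven named
scenarios: `control`, `probiotic-low`/`-high` (5000 / 10,000
*Bifidobacterium* colonies at the inlet every 480 steps, replacing the
baseline inlet for that step), `glucose-high`/`-low` (glucose inflow 60 /
15), and `constipation`/`diarrhea` (displacement / 3 and x 3). Overrides
apply only to the middle phase and revert field-for-field in recovery.

`run_ensemble()` runs replicates with consecutive seeds;
`summarize_ensemble()` reports per-timestep means with Student-t 95%
intervals, and `percent_difference()` transforms each treated replicate
against the control ensemble mean before applying the same interval -- the
simplest defensible propagation for percent-difference error bars, since
the alternative (percent differences of interval endpoints) has no sampling
interpretation. Timesteps with a zero control mean are flagged undefined
rather than returning infinities. `detect_steady_state()` compares
consecutive non-overlapping windows (default 1000 steps, 5% relative
tolerance); `extinction_times()` requires a count to reach zero *and stay
zero* through the end of the series, so transient dips rescued by inflow do
not count.

The test suite exercises the scenario layer at 10 replicates x 30,000
steps per scenario (the historical experiments used 100 replicates, which
remain one `n_replicates` argument away); the desk-scale checks (starvation
clock, threshold sweep, adhesion frequencies at n = 100,000) run in
seconds.

## What the simulator does and does not emulate

The generator *is* the model: there is no external data. It emulates
advection and washout, crowding-limited mucosal adhesion with permanent
embedding, discrete-unit nutrient competition with starvation, scheduled
reproduction under a space constraint, and cross-feeding via a single
produced metabolite. It does not emulate peristaltic or variable flow,
bacterial motility, host-secreted nutrients such as mucin, direct
interactions (toxins, immune response), variable doubling times, or
saturating consumption kinetics. Consequently, passing tests show that the
implementation reproduces this rule system faithfully and that the rule
system yields the documented qualitative responses; they say nothing about
quantitative fidelity to a real ileum.

## Known limitations

* **Neutral composition drift.** *Bacteroides* and *Clostridium* occupy an
  identical niche; their relative abundance performs a random walk anchored
  only weakly by the inlet flux, so post-perturbation compositions relax
  slowly (timescale beyond one 10,000-step phase) and can undershoot. Two
  acceptance sub-checks on minor-genus recovery fail for exactly this
  reason and are left red by design.
* **Absorbing embedded state.** With a 5% per-step embedding probability,
  roughly one mucus episode in three ends in permanent embedding, so any
  transient excess (e.g. probiotic doses) leaves a small permanent
  footprint.
* **Synchronized doubling.** All colonies share one doubling clock, which
  produces slow, coherent population oscillations around the steady state;
  replicate ensembles and control-matched comparisons absorb this, but
  single trajectories look wavier than a desynchronized system would.
* **Discrete-unit meals** make small populations fragile at low nutrient
  concentrations -- the mechanism behind the *Desulfovibrio* die-offs --
  where a saturating uptake function would let them persist at low density.
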