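# gutsim

An agent-based simulator of bacterial population dynamics on the wall of
the ileum, for researchers who want to explore *what-if* scenarios --
probiotic courses, dietary sugar changes, constipation, diarrhea -- in a
gut microbial community that is impractical to probe *in vivo*.

Four genera (*Bifidobacterium*, *Bacteroides*, *Clostridium*,
*Desulfovibrio*) compete for carbohydrates on a 1 × 100 lattice of wall
elements under constant unidirectional flow. Each agent is a bacterial
colony with an energy level, a continuous axial position, and an adhesion
state (free-flowing, mucus-bound, or permanently embedded). Per 26.3-second
timestep, a free colony adheres to the mucus layer with the
crowding-saturated probability

γ = γ_max · [1 − N/(N_mid + N)],

where N is the local colony count; mucus-bound colonies escape with
probability 0.10 or embed permanently with probability 0.05. Free colonies
and metabolites advect 0.278 elements per step and wash out past the distal
end. Hungry colonies (energy < 80/100) consume discrete metabolite units --
at most one per step, allocated uniformly at random when demand exceeds
supply -- gaining energy against a constant decay that starves a full
colony in exactly 1440 steps. At multiples of the 480-step doubling time,
colonies with energy > 50 divide under a per-element space constraint.
*Bifidobacterium* produces lactate when it feeds; *Desulfovibrio* lives on
that lactate alone, which makes it the community's sentinel for
cross-feeding effects.

## Worked example

Seed the reference community (10,000 colonies at 78.43 / 18.27 / 3.06 /
0.23%) and run the high-glucose-diet scenario -- three simulated days of
baseline, three with glucose inflow doubled from 30 to 60 units/step, three
of recovery:

```r
library(gutsim)

seed_world(default_config())
#> <gut_world> t = 0 | 9999 colonies | 0.0 metabolite units
#>   Bifidobacterium: 7843
#>   Bacteroides: 1827
#>   Clostridium: 306
#>   Desulfovibrio: 23

run_scenario("glucose-high", total_steps = 30000, seed = 1)
#> <gut_run> glucose-high | seed 1 | 30000 steps
#>  final counts: Bifidobacterium=9603, Bacteroides=1851, Clostridium=343, Desulfovibrio=33
```

The final counts sit close to the seeded composition: by the end of the
recovery phase the perturbation has washed out. The interesting signal is
*during* the perturbation. Compare a replicate ensemble against control,
late in the perturbation phase (timestep 19,000):

```r
ens  <- run_ensemble("glucose-high", n_replicates = 3, base_seed = 1)
ctrl <- run_ensemble("control",      n_replicates = 3, base_seed = 1)
pd   <- percent_difference(ens, ctrl)
subset(pd, timestep == 19000)
#>      timestep           genus pct_diff    lo    hi undefined
#> 191     19000 Bifidobacterium     38.9 37.36  40.5     FALSE
#> 492     19000     Bacteroides     37.7 27.11  48.3     FALSE
#> 793     19000     Clostridium     31.8  5.55  58.1     FALSE
#> 1094    19000   Desulfovibrio    116.5 97.59 135.3     FALSE
```

`pct_diff` is 100 × (treated − control mean)/control mean with a Student-t
95% interval across replicates. Doubling dietary glucose roughly doubles
*Desulfovibrio* -- a genus that cannot eat glucose at all -- because the
extra glucose consumed by *Bifidobacterium* raises lactate production; the
glucose consumers themselves respond far less. Halving glucose instead
drives the lactate supply below what the small *Desulfovibrio* population
needs, and it dies off completely (first zero at timestep 11,500, never
recovering):

```r
extinction_times(run_scenario("glucose-low", total_steps = 30000,
                              seed = 1)$series)
#> Bifidobacterium     Bacteroides     Clostridium   Desulfovibrio
#>              NA              NA              NA           11500
```

Scenarios: `control`, `probiotic-low`, `probiotic-high`, `glucose-high`,
`glucose-low`, `constipation`, `diarrhea`. Each `gut_run` carries the genus
time series, per-element spatial profiles (heatmap-ready), four key spatial
snapshots straddling the perturbation boundaries, and a per-step event log.
`write_outputs()` exports an ensemble as tidy CSVs plus a manifest with the
seeds and config checksum needed for an exact rerun. A command-line
wrapper is installed at `inst/cli/gutsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gutsim.R", package="gutsim"))')" \
    run --scenario constipation --replicates 10 --steps 30000 --seed 1 \
    --record-interval 100 --out results/constipation
```

Configuration is a YAML (or JSON) file mirroring `default_config()`
field-for-field; every parameter -- genus definitions, metabolite web,
adhesion, energy, flow, seeding -- is overridable
(`gutsim validate-config file.yaml` checks one).

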