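# hpbrush

Coarse-grained molecular dynamics of globular protein adsorption on
polymer-coated surfaces, in R (with compiled kernels).

Polymer coatings — chains end-tethered to a surface — are a standard way to
tune whether proteins stick to a material. `hpbrush` implements a generic
bead-spring model of this system for people who want to explore the design
space (grafting density, wall attraction, protein size and hydrophobicity,
attractive doping sites) without atomistic cost: hydrophobic-polar (HP)
model proteins, FENE bead-spring coatings tethered to an implicit 9-3 wall,
explicit coarse-grained water, NVT/NVE dynamics, and a free-energy pipeline
(steered-MD umbrella sampling + WHAM).

## The model in brief

All quantities are in reduced LJ units (bead mass, bead diameter, kBT).
Beads interact through truncated-shifted Lennard-Jones potentials
`eLJrc`: V(r) = 4e[(r^-12 − r^-6) − (rc^-12 − rc^-6)], the WCA repulsion
being `1LJ2^(1/6)`. Backbones are FENE springs (kFENE = 30, RFENE = 1.5)
plus the WCA core (Kremer–Grest convention). Walls act through the 9-3
potential `eWzc`: W(z) = e[(2/15)z^-9 − z^-3 − (2/15)zc^-9 + zc^-3], ranked
by the effective strength I = ∫ exp(−W) dz over (0, zc]. Proteins are
Np-bead chains with round(hp·Np) mutually attractive hydrophobic beads
(`120LJ1.19`) in a random sequence; everything else about them
is repulsive. Observables: gyration radius and end-to-end distance, coating
height, adsorbed fraction (protein COM below hmax − Rg_p), z-density
profiles, gyration-tensor asphericity, and PMF(z) = −kBT ln P(z)/P(z0)
from WHAM over 61 harmonic-bias windows.

## Worked example

A miniature version of the central experiment — do proteins adsorb more on
a more attractive surface?

```r
library(hpbrush)

# rank four wall types by effective interaction strength
walls <- c("1W1", "3W1", "1W1.5", "3W2.5")
sapply(walls, function(w) {
  s <- parse_interaction_name(w)
  round(effective_wall_strength(s$epsilon, s$zc), 3)
})
#>   1W1   3W1 1W1.5 3W2.5
#> 0.307 0.349 1.184 7.422

# a small coating + 2 HP proteins + water, strongly attractive wall
sys <- make_fixture("mini-adsorption", seed = 1)
sys
#> particle system: 518 beads, 103 bonds, box 12 x 12 x 12
#>   types: R_tethered=9, R=81, w=404, H=6, P=18
#>   mobile: 509, immobile: 9
sys$itable <- interaction_table(wall = "3W2.5")
tr <- run_md(sys, integrator_config(steps = 100000,
                                    thermostat = "nose-hoover",
                                    sample_every = 1000))
prot <- which(tr$role == "protein")
rg_p <- mean(sapply(split(prot, tr$mol[prot]), function(ix)
  chain_metrics(tr$frames[ix, , dim(tr$frames)[3]])$Rg))
ads <- adsorbed_fraction(tr, Rg_p = rg_p)
stationary_average(ads$fads, 0.3)$mean
#> [1] 0.484
```

Under the strongest wall (`3W2.5`, I = 7.42) about half of the
protein-frames in the stationary window count as adsorbed (COM below the
coating height minus the protein gyration radius); rerunning with the
weakest wall (`1W1`, I = 0.307) gives 0 — the qualitative ordering the
model is built to capture. Across all eight tabulated wall types this
ordering holds with Spearman rank correlation 0.78 on this miniature
system.

A command-line front end for shell pipelines (`build`, `run`, `umbrella`,
`wham`, `analyze`, `fixture` subcommands) is installed at
`inst/cli/hpbrush`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the effective wall
interaction strengths for four wall types (t1–t4, adaptive quadrature of
∫ exp(−W) dz), and the stationary gyration radius of a single S25 protein
(Np = 40, hp = 25%) in explicit water at n = 0.65, run with the full reference
protocol (NVT T = 1, dt = 0.005, 10^6 steps from a rodlike
start, trailing-30% average) (t11). Runtime is dominated by the protein
run (a few minutes); results are written as JSON.

Note: the stationary protein size this model produces differs from the
tabulated reference value — the hydrophobic core forms, but nothing in the
stated interaction matrix condenses the polar corona. The vignette's
"Known limitations" section analyses this in detail; the script reports
the computed value as is.
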