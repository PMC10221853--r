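---
title: "Coarse-grained modelling of globular protein adsorption on polymer coatings"
author: "hpbrush"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of globular protein adsorption on polymer coatings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpbrush)
```

## The model

`hpbrush` simulates the adsorption of globular proteins on polymer-coated
surfaces with a generic bead-spring model in reduced Lennard-Jones units:
unit bead mass, unit bead diameter, and unit energy $k_BT$.

**Geometry.** A rectangular box, periodic in $x$ and $y$, bounded by two
implicit planar walls at $z = 0$ (the tethering surface) and $z = H$. The
full-scale geometry is $54.29 \times 64.44 \times 20$, giving a tethering
area $A = 3498.4$. Bulk boxes (periodic in $z$ as well, no walls) are used
to equilibrate single proteins.

**Coating.** $G$ flexible chains of $N$ beads, each permanently tethered by
its first bead to the lower wall on a uniform near-square lattice; the
grafting density is $\sigma = G/A$. The regimes studied are the mushroom
($\sigma = 0.023$, $G = 81$), intermediate ($0.056$, $196$) and brush
($0.087$, $306$), classified by comparing the measured squared gyration
radius with the area per chain $\Sigma = 1/\sigma$ (brush when
$R_g^2 > \Sigma$).

**Proteins.** The hydrophobic-polar (HP) model: each protein is a linear
chain of $N_p$ beads, a fraction $h_p$ of which (exactly
$\mathrm{round}(h_p N_p)$, at seeded-random sequence positions) are
hydrophobic H beads, the rest polar P beads. H beads attract each other; all
other protein interactions are purely repulsive. Four protein types follow
the reference setup: S25/S35 ($N_p = 40$) and L25/L35 ($N_p = 60$) with
$h_p = 25\%$ or $35\%$.

**Interactions.** Non-bonded pairs interact through the truncated-shifted
Lennard-Jones potential $\epsilon\mathrm{LJ}r_c$,
$$V(r) = 4\epsilon\left[(r^{-12} - r^{-6}) - (r_c^{-12} - r_c^{-6})\right],
\quad r \le r_c,$$
which reduces to the purely repulsive WCA potential for $\epsilon = 1$,
$r_c = 2^{1/6}$. The default interaction matrix: every pair is WCA except
the hydrophobic attraction H-H ($120\mathrm{LJ}1.19$ as printed, a
$\sim$10.5 $k_BT$ well after truncation-shift; both parameters are
config-exposed because the notation is unusual) and the doped A-P attraction
($\{1,3\}\mathrm{LJ}1.5$). Walls act through the integrated 9-3 potential
$\epsilon\mathrm{W}z_c$,
$$W(z) = \epsilon\left[\tfrac{2}{15} z^{-9} - z^{-3}
 - \tfrac{2}{15} z_c^{-9} + z_c^{-3}\right], \quad z \le z_c,$$
with minimum at $z = (2/5)^{1/6} \approx 0.858$; cutting there gives the
purely repulsive wall used for coating, water and A beads and for the upper
wall. Protein beads feel the attractive wall $\epsilon \in \{1,3\}$,
$z_c \in \{1, 1.5, 2, 2.5\}$; the eight types are ranked by the effective
strength $I = \int_0^{z_c} e^{-W(z)}\,dz$ (`effective_wall_strength()`).
Backbone bonds are FENE springs ($k_{FENE} = 30$, $R_{FENE} = 1.5$)
combined with the repulsive WCA core, and bonded neighbours are excluded
from the tabulated pair interaction — the Kremer-Grest convention as
implemented by LAMMPS (`bond_style fene` with `special_bonds fene`), which
the reference simulations used. Applying the tabulated H-H well inside a
bond instead stores $\sim$178 $k_BT$ of $\epsilon = 120$ repulsion at the
0.96 startup bond length and snaps the FENE spring immediately; this
convention choice is therefore forced, not stylistic.

**Water.** Explicit monomeric WCA beads filling the box to total bead
number density $n = 0.65$ (dense liquid). Water is inserted on a jittered
simple-cubic lattice rather than by random sequential insertion, which jams
below this density; the jitter amplitude provably preserves the minimum
pair distance of 1.

**Doping.** Attractive A beads toward the polar protein beads, in five
placements: none, the middle backbone bead ($\lceil N/2\rceil$, one per
chain), a random non-tethered bead per chain, the free-end bead, or
immobile ligand beads on a lattice at altitude $z = 3$ with surface density
$\sigma_{lig} \in \{0.023, 0.01\}$, each ligand replacing the nearest water
bead so the total bead count is conserved.

## Dynamics

Velocity-Verlet integration with $\Delta t = 0.005$ at $T = 1$, controlled
by a single Nose-Hoover thermostat (quarter-step splitting; thermostat mass
$Q = g T \tau^2$ from the mobile degrees of freedom $g$ and the damping
time $\tau = 1$) or by a Langevin thermostat (BAOAB splitting, seeded,
bit-reproducible) as a desk-scale alternative. Immobile beads — tethers and
ligands — have forces reported but are never moved, and tethered beads feel
no wall. Neighbor search uses an $xy$-periodic cell list with a 0.3 skin,
rebuilt on half-skin displacement, falling back to an all-pairs sweep for
boxes thinner than three cells. A bead escaping past a wall, a FENE bond
reaching $R_{FENE}$, or a velocity blow-up aborts the run with a bead
diagnostic; $z$-confinement relies on wall forces alone.

## Observables

* `chain_metrics()`: $R_g^2 = N^{-1}\sum_i (r_i - r_{cm})^2$, end-to-end
  distance, and chain height $h = \max_i z_i$; `dry_height()` gives the dry
  reference $h_{dry} = \sigma N / n$.
* `adsorbed_fraction()`: a protein is adsorbed when its center of mass lies
  below $h_{max} - R_{g,p}$. The coating height reference is recomputed
  per frame by default because adsorption itself shifts the coating height;
  a fixed reference is a parameter.
* `density_profile()`: bead counts per $z$ bin normalized by
  $A\,\Delta z\,n_{frames}$ (default $\Delta z = 0.2$), so the bin sum
  recovers the mean selected-bead count.
* `asphericity()`: gyration-tensor shape descriptor
  $\alpha = [(R_1-R_2)^2 + (R_2-R_3)^2 + (R_3-R_1)^2] / [2(R_1+R_2+R_3)^2]$
  computed from the tensor *eigenvalues*, which makes $\alpha$ rotation
  invariant and pins the limits $\alpha = 1$ (rod) and $\alpha = 0$
  (spherical symmetry) exactly; the raw diagonal elements do not, and the
  divergence between the two readings is reported as a diagnostic.
* `stationary_average()`: trailing-30% averages, the convention used for
  all stationary quantities.

## Umbrella sampling and WHAM

The free energy of adsorption along $z$ comes from steered MD: the center
of mass of a single protein is tethered toward the wall by a harmonic
spring $w_j(z) = (k_j/2)(z - l)^2$ with rest length $l = 1$ and stiffness
ascending $k_j = j\,\Delta k$ ($\Delta k = 0.005$ up to $0.3$, i.e. 61
windows; beyond $k = 0.3$ the stationary spring extension no longer
changes). Each window runs $t = 500$ and records the COM altitude every 10
steps ($10^4$ samples); windows ascend in $k$, each starting from the
previous window's final state, preceded by an un-recorded 10% equilibration
segment (config-exposed) so the production segment still yields exactly
$10^4$ samples.

`wham_solve()` iterates the self-consistent histogram equations
$$P(z) = \frac{\sum_j g_j^{-1} h_j(z)}
              {\sum_j N_j g_j^{-1} e^{-\beta (w_j(z) - f_j)}},
\qquad e^{-\beta f_j} = \int_0^{L_z} e^{-\beta w_j(z)} P(z)\,dz,$$
with $g_j = 1$ by default (the autocorrelation correction
$g_j = (1+2\tau_j)^{-1}$ is accepted as window metadata), bin width 0.1
over $(0, L_z)$, gauge fixed at $f_1 = 0$, and convergence declared at
$\max_j |\Delta f_j| < 10^{-6}$. The PMF is
$\mathrm{PMF}(z) = -\beta^{-1}\ln[P(z)/P(z_0)]$ — note the minus sign of
the standard estimator; the source formula as printed lacks it, which
would turn probability maxima into free-energy maxima. The default
reference $z_0$ is the sampled bin farthest from the wall (bulk). A single
unbiased window reduces exactly to the log-histogram estimate, which the
tests assert.

## Numerical choices

* Quadrature for $I$: adaptive (`stats::integrate`, relative tolerance
  $10^{-10}$) with the integrand forced to 0 at the wall plane; $W$ is
  capped at 750 where $e^{-W}$ underflows to exactly 0 in double precision.
  All eight tabulated values reproduce to the printed 3 decimals.
* Overflow guards: pair and wall evaluations reject separations below
  $10^{-6}$ instead of returning `Inf`.
* Rodlike starts use the FENE+WCA equilibrium bond length 0.96 (computed by
  1-D minimization). A full-scale chain ($49 \times 0.96 \approx 47$)
  cannot stand vertically under $H = 20$, so rods are tilted in the
  $xz$-plane to fit below $0.9H$; a tilted rod that would wrap onto its own
  periodic image is a construction error.
* The middle bead for even $N$ is the 1-based index $\lceil N/2 \rceil$
  (25 for $N = 50$); random doping excludes the tether but may select the
  free end.
* Protein placement uses a uniform $xy$ grid, uniform random in-plane
  rotation, clearance 1.0 above the measured coating height, and bounded
  retries against the minimum-distance constraint.
* Water velocities are Maxwell-Boltzmann at $T = 1$ with the net momentum
  of the mobile beads removed.
* Degrees of freedom for the kinetic temperature count mobile beads only
  ($g = 3N_{mobile}$); the conserved-momentum correction is below the
  reported precision for every system used here.

## What the miniature fixtures do and do not establish

The test fixtures (`make_fixture()`) are deliberately small: a 2-bead
dimer; a $12^3$ box with a $3\times3$ coating of 10-mers, two 12-bead
proteins and water at $n = 0.65$ ("mini-mushroom") or $n = 0.3$
("mini-adsorption", the light variant used to run all eight wall types
within the test budget); a single 12-mer protein box; and a dilute water
slab. Green tests on these establish integrator correctness (energy
conservation, thermostat temperature, determinism), construction
invariants, and qualitative physics (hydrophobic collapse, the ordering of
adsorption with wall strength). They do not establish quantitative
agreement with full-scale reference adsorption curves, which require $4.5\times10^4$
beads and $10^8$ steps; the full-scale systems are constructible with this
package but not run in the test suite.

The WHAM acceptance check uses a synthetic world instead of MD: biased
samples drawn from the exact per-bin Boltzmann probabilities of a known
cosine double well (wells at $z = 3$ and $7$, 2 $k_BT$ barrier). The
amplitude is chosen so that, at the protocol's $61 \times 10^4$ samples,
every bin keeps enough pooled counts that the Poisson floor sits well below
the 0.1 $k_BT$ recovery band — the check then measures estimator
correctness, not sample-size limits.

## Known limitations

* **The printed protein size is not reproduced.** Running the reference
  single-protein protocol verbatim (S25: $N_p = 40$, $h_p = 25\%$, explicit
  WCA water at $n = 0.65$, Nose-Hoover $T = 1$, $\Delta t = 0.005$, $10^6$
  steps from a rodlike start) yields a stationary $R_g \approx 3.1$: the
  10-bead hydrophobic core forms (and by the end of the run sits interior
  to the polar beads), but
  the 30 polar beads — athermal toward everything in the stated interaction
  matrix — remain swollen loops. The tabulated value $R_{g,p} = 1.9$ is the
  size of a *fully* compact 40-bead globule, which requires a compaction
  mechanism acting on the polar corona that the stated interactions do not
  contain. A purely repulsive 40-mer in the same water measures
  $R_g^2 = 18.7$ here, matching athermal excluded-volume statistics. The
  discrepancy is reported honestly by the acceptance machinery rather than
  calibrated away; the H-H parameters are config-exposed for users who wish
  to explore alternative readings of the printed interaction.
* The Nose-Hoover implementation is a single thermostat, not a chain;
  ergodicity for very small or stiff systems relies on the surrounding
  fluid.
* Truncated attractive interactions have discontinuous forces at their
  cutoffs (as in the reference toolchain); NVE energy conservation is
  checked on equilibrated states where crossing events are rare.
* No electrostatics, no barostat, no bond constraints, single-CPU kernels.
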