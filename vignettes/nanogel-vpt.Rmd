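---
title: "Modelling the volume phase transition of a PNIPAM nanogel with DPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the volume phase transition of a PNIPAM nanogel with DPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdgel)
```

## The model

Poly(N-isopropylacrylamide) (PNIPAM) gels collapse when heated past their
lower critical solution temperature (~305 K): below it water is a good
solvent and the network swells; above it the solvent-mediated hydrophobic
effect wins and the network expels water and compacts. `dpdgel` models an
isolated, neutral PNIPAM nanogel in explicit coarse-grained water with
dissipative particle dynamics (DPD), where the entire temperature
dependence enters through measurable quantities: the water density and
isothermal compressibility, and a fitted Flory–Huggins interaction
parameter

$$\chi(T) = 0.5 + A\left(1 - \frac{\Theta}{T}\right),
\qquad A = 35.2,\ \Theta = 308.3\ \mathrm{K},$$

which crosses the athermal value 0.5 exactly at the theta temperature.
No explicit attraction between monomers is needed: heating raises $\chi$,
which raises the water–monomer repulsion, and the hydrophobic collapse
emerges from solvent exclusion alone. An implicit-solvent Langevin mode
(WCA beads plus a temperature-dependent attraction) is included as the
conventional point of comparison.

## DPD in two sentences

Beads interact through a soft linear repulsion
$F^C(r) = F^{max}_{ij}(1 - r/r_c)$ inside a cutoff $r_c$, plus a pairwise
friction $-\gamma(\hat r \cdot v_{ij})\hat r$ and a pairwise random force
$\sigma \theta_{ij}\hat r/\sqrt{\Delta t}$ that together form a
momentum-conserving thermostat; the fluctuation–dissipation theorem fixes
$\sigma^2 = 2\gamma k_BT$. Because both thermostat forces act along pair
vectors, hydrodynamics is preserved — the property that lets the solvent
mediate collapse realistically.

## Parameterization with unequal bead volumes

One water bead lumps $N_m = 5$ water molecules; one monomer bead is one
NIPAM monomer. With the bulk PNIPAM density (1.1 g/cm³, molar mass 113.16
g/mol) the monomer bead volume (~171 Å³) is close to the 5-water bead
(~150 Å³), but not equal — the parameterization must therefore handle
unequal pure densities. The chain of quantities, all computed by
`build_forcefield()`:

1. **Cutoff.** Imposing reduced density $\tilde\rho = 3$ fixes
   $r_c = (\tilde\rho N_m m_w/\rho_w(T))^{1/3}$ — about 7.66 Å at 298 K,
   drifting with the water density; $r_c$ is also the length unit.
2. **Water self-repulsion.** Compressibility matching,
   $F^{max}_{ww} = (N_m\tilde\kappa^{-1} - 1)/(2\alpha\tilde\rho)$ with
   $\tilde\kappa^{-1} = 1/(\rho_w k_BT \kappa_T)$ and $\alpha = 0.101$
   from the DPD equation of state. At $N_m = 1$,
   $\tilde\kappa^{-1} \approx 16$ this collapses to the classic
   repulsion 25.
3. **Matching pressure.** The equation of state is inverted at the water
   point, $p = \tilde\rho + \alpha F^{max}_{ww}\tilde\rho^2$; this
   bookkeeping pressure (not the physical pressure) transfers the
   repulsion scale to other bead types.
4. **Monomer self-repulsion.** $F^{max}_{mm} = (p -
   \tilde\rho_m)/(\alpha\tilde\rho_m^2)$ at the monomer's own pure
   reduced density.
5. **Cross repulsion.** A geometric-mean baseline
   $\sqrt{F^{max}_{ww}F^{max}_{mm}}$ plus a $\chi$-linear excess with the
   0.0454 constant and pure-density weighting,
   $$F^{max}_{wm} = \sqrt{F^{max}_{ww}F^{max}_{mm}} +
   \frac{\chi(T)\,p}{0.0454\,(F^{max}_{ww}\tilde\rho_w +
   F^{max}_{mm}\tilde\rho_m)}.$$
   At $\chi = 0$ unlike beads repel at the geometric mean; for two
   identical classic water beads the excess slope is ≈ 3.8 per unit
   $\chi$, the same order as the classic $\Delta a \approx 3.27\chi$
   proportionality. The published rendering of this expression is
   typographically ambiguous, so the whole excess term is isolated inside
   `fmax_cross()`: if a different reading proves correct, one function
   changes and no caller does.

```{r}
forcefield_table(c(280, 300, 310, 330))
```

A subtlety worth stating explicitly: reduced forces at different
temperatures are expressed in different units, because the force unit
$k_BT/r_c$ itself grows ~18% over 280–330 K. On the physical force scale
the self-repulsions rise and then plateau above ~305 K while the
water–monomer repulsion keeps climbing through 330 K — the
induced-hydrophobicity signature. On the reduced scale $F^{max}_{wm}$
peaks near 310 K instead; cross-temperature trends should always be read
from the physical column (`fmax_wm_pN` above).

Friction is global, $\tilde\gamma = 4.5$, for every pair type (per-pair
friction only matters for transport properties, which are out of scope),
giving $\sigma = 3$ exactly.

## The nanogel network

The topology is diamond-like: crosslinker sites on a tetrahedral lattice,
every nearest-neighbour pair of sites joined by a chain of 8 monomer
beads, and the whole construct pruned to a sphere so that boundary
crosslinkers keep 1–3 chains and boundary chains up to 8 monomers. The
generator itself is unconstrained by any published recipe beyond those
invariants, so the packaged default was calibrated once: lattice extent 2,
pruning centre at $0.135\,(1,1,1)$ (a point on a central bond — slightly
off the midpoint, which breaks shell degeneracies so the bead count moves
in steps of one) and pruning radius 0.91 lattice units, giving exactly
439 polymer beads (32 crosslinkers + 407 monomers, 450 bonds). That
topology is also committed as a plain-text fixture
(`inst/extdata/nanogel439_*.csv`) to pin bead numbering for regression
tests.

```{r}
gel <- build_nanogel()
gel
str(validate_topology(gel))
```

Bonds are harmonic, $U = \tfrac{K}{2}(r - r_0)^2$ with $K = 0.4$ N/m and
$r_0 = 6.5$ Å, shared by both engines. Crosslinkers interact exactly like
monomers apart from their bond count.

### Initial configurations

`initial_configuration()` embeds the network at the box centre —
crosslinker sites at 2.2 $r_c$ spacing, chains bent onto circular arcs so
every initial bond is 0.65 $r_0$ long (inside the $[0.5\,r_0, 2\,r_0]$
construction window) — and fills the rest with water at reduced density 3
by random insertion, rejecting positions closer than 0.3 $r_c$ to any
polymer bead. Soft DPD potentials tolerate the remaining overlaps; the
thermalization stages relax them. For the published 22.5 $r_c$ box the
density-derived water count is $3 \times 22.5^3 - 439 = 33{,}733$, about
0.3% above the published 33,620 — the printed split presumably applies a
small volume correction for the polymer that is not stated, so the builder
exposes `water_count` as an explicit override and defaults to the
density-derived value.

## Integration

The compiled core integrates velocity Verlet with one force evaluation
per step, the dissipative force using the half-step velocities. Choices
that matter:

* **Random-force scaling** $1/\sqrt{\Delta t}$, required for a
  time-step-independent temperature.
* **Noise distribution**: $\theta_{ij}$ uniform on $[-\sqrt3, \sqrt3]$
  (zero mean, unit variance), one draw per pair per step, equal and
  opposite on the partners — momentum is conserved exactly per pair.
* **No exclusions**: bonded pairs also feel the non-bonded forces; soft
  potentials make exclusions unnecessary.
* **Coordinates**: wrapped positions plus per-bead image counters, so
  pair distances use the minimum image while the radius of gyration uses
  unwrapped coordinates from the same arrays.
* **Determinism**: a private xorshift RNG seeded from the protocol seed,
  with a fixed pair iteration order, makes trajectories bit-reproducible;
  the neighbour list is a Verlet list (skin 0.3 $r_c$) over a cell grid,
  rebuilt when any bead moves half the skin, and its cell-list forces are
  tested to equal a brute-force all-pairs reference to machine precision.
* **Time step** $\Delta t = 0.01\,\tilde t$ as in the full-scale
  protocol; a step moving any bead more than half the box raises a
  blow-up error carrying the step index.

The full-scale protocol is $10^6$ Langevin pre-thermalization steps,
$10^6$ DPD thermalization steps and $5\times10^6$ production steps. The
desk-scale defaults used in the test suite scale this down (see below).

## Implicit-solvent comparison mode

`langevin_forcefield()` swaps the explicit solvent for a per-bead Langevin
thermostat, WCA excluded volume ($\sigma = 6.5$ Å — the bond-length
scale), and a hydrophobic attraction between monomers. The published
source for those constants is not reproducible from the main text, so the
attraction is the package's own documented stand-in: a cosine-smoothed
square well, flat at depth $\epsilon_h(T)$ out to $2^{1/6}\sigma$ and
smoothly closing at $2\sigma$, with
$\epsilon_h(T) = 0.026\,(T - 270\ \mathrm{K})$ in $k_BT$ units — zero
below the onset, ~1.6 $k_BT$ at 330 K, deep enough to collapse the
network above the transition while leaving it swollen at 280 K. Damping
is 1 (reduced) by default. These defaults make the Langevin mode a
qualitative comparison: its transition temperature depends directly on
the chosen slope, unlike the DPD mode where the transition is inherited
from the fitted $\chi(T)$.

## Observables

* `rg_series()` / `radius_of_gyration()` — equal-mass RMS distance from
  the centroid, on unwrapped coordinates (wrapped input is detected
  through bonds longer than half the box and rejected).
* `block_sem()` — blocking analysis for correlated series: the SEM is
  the mean of the blocking curve over the 12–25-block window, where
  blocks of a well-sampled run are effectively independent.
* `rdf_pair()` / `rdf_from_point()` — shell-count histograms normalized
  by the ideal-gas expectation (distinct-pair convention for identical
  groups; default bin 0.1 $r_c$; frames weighted equally). The
  point-reference variant uses the polymer centre of mass computed on
  unwrapped coordinates, then re-wrapped — this avoids the periodic-COM
  artifact for a compact cluster.
* `swelling_ratio()` — $R_g(T)/R_g(T_{ref})$, reference = lowest
  temperature.
* `first_peak_position()` — first local maximum above $g = 1$, refined
  by parabolic interpolation through three bins (resolves peak shifts
  smaller than the bin width).
* `max_diameter()` — largest $r$ with $g(r)$ above a threshold
  (default $10^{-3}$); for an isolated cluster the monomer–monomer
  $g(r)$ tail ends at the cluster span.
* `transition_temperature()` — the consecutive temperature pair with the
  largest $R_g$ drop; degenerate (flat/linear) inputs are flagged, and
  monotone non-decreasing input returns the no-transition sentinel.

## What the desk-scale experiment shows — and what it does not

The acceptance suite runs a reduced version of the study: the same
439-bead network in a 12 $r_c$ box (5,184 beads) for $2\times10^5$
production steps at 280 K and 330 K, after $4\times10^3$ Langevin and
$1.2\times10^4$ DPD thermalization steps. Problem sizes were chosen so the
full suite completes on one CPU while each run still covers ~2,000 reduced
time units — long enough for the 330 K collapse (strong driving) and for
the 280 K swelling to separate cleanly. At these settings the three
signatures of the transition all appear with wide margins: mean $R_g$
drops from ~40 Å (280 K) to ~22 Å (330 K); the centre-of-mass-to-water
$g(r\to0)$ falls from ~1 to ~0.1; and the first solvation-shell peak of
the monomer–water $g(r)$ falls by half.

What scaled-down runs do **not** show: quantitative agreement with the
full-scale mean radii (the 12 $r_c$ box compresses the swollen state —
the 280 K gel at full scale reaches $R_g \approx 44$ Å $ = 5.7 r_c$,
whose periodic images interact in a 12 $r_c$ box), equilibrated error
bars, or the 305–310 K bracket from simulation (that needs all nine
temperatures at full scale). The full 22.5 $r_c$, $7\times10^6$-step
protocol per temperature is reachable through `run_from_config()` with
the packaged defaults and is expected to take days per temperature on one
CPU; the published per-temperature means are shipped as a reference table
(`reference_rg()`) and the analysis layer reproduces the published
swelling ratio (0.454 at 330 K) and transition bracket (305–310 K) from
it.

## Numerical choices and degenerate inputs

* Temperatures outside the packaged water table (273–373 K) are a range
  error, not an extrapolation.
* `fmax_water()` rejects $N_m\tilde\kappa^{-1} \le 1$ (ideal-gas limit);
  `fmax_self()` rejects matching pressures below the ideal-gas pressure
  (negative repulsion).
* Exactly coincident beads exert no pair force (no defined direction);
  the WCA force is capped at $10^4$ near contact to survive random
  initial placements.
* RDF bins must be positive and the histogram range at most half the
  box; `block_sem()` requires at least twice `max_blocks` points.
* The kinetic temperature subtracts centre-of-mass motion and divides by
  $3(N-1)$ degrees of freedom.

## Known limitations

* Hydrogen bonding, electrostatics and charged/ionizable monomers are
  outside the model; the collapse mechanism here is purely the
  $\chi$-driven solvent exclusion.
* Transport properties are not meaningful with a single global friction.
* The single-force-evaluation DPD–velocity-Verlet integrator carries a
  small, $dt$-dependent kinetic temperature bias (≲1% at
  $\Delta t = 0.01$ with these repulsions), visible in the thermostat
  tests; it does not affect the structural observables at the reported
  tolerances.
* The Langevin mode's hydrophobic well uses package-chosen constants, so
  only its qualitative behaviour (collapse with heating) is comparable.
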