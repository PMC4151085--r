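---
title: "Modeling global-to-core planar cell polarity coupling via oriented microtubules"
author: "wingpol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling global-to-core planar cell polarity coupling via oriented microtubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingpol)
```

# The biological question

In the developing fly wing, every epithelial cell points the same way: each
grows a single hair at its distal vertex. Two molecular systems cooperate to
achieve this planar cell polarity (PCP). The *core* module (Frizzled (Fz),
Dishevelled (Dsh), Van Gogh (Vang), Prickle (Pk), with Flamingo on both
sides) segregates into distal (Fz, Dsh) and proximal (Vang, Pk) membrane
domains through local feedback, but needs a tissue-scale cue to know which
way is distal. The *global* Ft/Ds/Fj module — the atypical cadherins Fat
(Ft) and Dachsous (Ds), whose trans-binding is tuned by the Golgi kinase
Four-jointed (Fj) — reads tissue-level expression gradients. `wingpol`
implements a mechanistic bridge between the two: junctional Ft-Ds
heterodimer asymmetry orients an apical, non-centrosomal microtubule (MT)
network, and MT plus-end-directed transcytosis of Dsh-containing vesicles
delivers the directional bias that the core feedback then amplifies.

The package has two halves:

1. a cell-grid ODE model of the coupled Ft/Ds/Fj -> MT -> core PCP system
   (`hex_grid()`, `solve_ftds_layer()`, `mt_bias_from_ftds()`,
   `simulate_core()`, `pcp_pipeline()`), and
2. the quantification toolkit such experiments use, with synthetic-data
   generators for every stage (structure-tensor orientation fields and
   axial rose plots, cross-correlation shift colocalization, anchoring-site
   circular statistics, vesicle-track direction and motion-mode
   classification).

# The lattice and the Ft-Ds layer

Cells are pointy-top hexagons on an `n_rows x n_cols` lattice (default
6 x 30), with outward edge normals at 0, 60, ..., 300 degrees; 0 degrees =
+x = distal. Apposed edges of neighboring cells form junctions.

**Boundaries.** Outer edges pair with a virtual mirror image of their own
cell. The alternative — leaving outer edges without partners — breaks the
per-cell symmetry of boundary cells: a uniform tissue would then polarize
spontaneously from its edges, which contradicts both intuition and the
symmetry properties the tests verify (`|P| = 0` in a uniform field, zero
bias under uniform Ds/Fj, for *every* cell). The mirror convention keeps
uniform tissue exactly symmetric while still preventing any flux through
the boundary. `solve_ftds_layer(boundary = "open")` restores the literal
no-partner behavior for comparison.

**Binding equilibrium.** Per junction, heterodimers form by mass action:
the forward rate for Ft of cell $i$ binding Ds of neighbor $j$ is
$k_{on} a_F(Fj_i)\, a_D(Fj_j)\, \mathrm{Ft}^{free}_i\, \mathrm{Ds}^{free}_j$
with $a_F(F) = 1 + \alpha_F F$ (Fj activates Ft) and
$a_D(F) = 1/(1 + \alpha_D F)$ (Fj inhibits Ds); unbinding at $k_{off} H$.
Free pools are well mixed per cell and fixed totals are conserved. The
layer is quasi-static — gradients are inputs, and the equilibrium is
found by relaxing the true kinetics in pseudo-time until the maximal rate
falls below `tol` (default 1e-11). Damped fixed-point iteration was tried
first and oscillates for steep gradients; kinetic relaxation is
unconditionally stable here because fluxes vanish smoothly as free pools
empty.

Opposing tissue gradients of Ds (high proximal) and Fj (high distal) make
each cell bind more Ft on its proximal side. The per-cell bias vector
$b_i = -\sum_e H_{i,e}\, \hat n_e$ then points distally — away from the
Ft-rich membrane, where MT minus ends anchor, i.e. toward MT plus ends.
With a steep Ds step and flat levels beyond it, the junctional asymmetry
decays within a column or two of the step (`measure_propagation_columns()`,
default threshold 5% of the maximal column mean): the layer itself has no
strong feedback, so the global cue is local.

# The microtubule bias

`mt_bias_from_ftds()` converts the layer into per-cell delivery weights
$m_{i,e}$ (fraction of directed vesicle traffic arriving at edge $e$):

* `coupled`: $m \propto \epsilon + [b_i \cdot \hat n_e]_+^q$ with floor
  $\epsilon = 0.2$ and exponent $q = 1$. The floor keeps delivery strictly
  positive on every edge and bounds how strongly the MT architecture can
  imprint on the steady state; it was chosen (once) so that the *direction*
  of the bias is faithfully transmitted while its *magnitude* stays a
  perturbation — which is what makes the steady state insensitive to the
  gradient shape.
* `random`: uniform 1/6 — unoriented MTs.
* `oriented_unbiased`: exactly 1/2 on each of the two P-D edges — MTs
  P-D-oriented but with no plus-end excess, as seen in the distal pupal
  wing.
* `imposed`: user weights.

A per-cell mode vector lets different regions carry different
architectures (e.g. `coupled` proximally, `oriented_unbiased` distally).

# The core reaction network

Per cell: cytoplasmic Dsh, Pk and Vang pools. Per edge: free membrane Fz
and Vang, free membrane Dsh, Dsh-Fz complexes, Pk-Vang clusters; per
junction: intercellular Fz-Vang bridges, Dsh-bound or not. The reactions
(rates in `core_params()`):

1. **Transport.** Cytoplasmic Dsh is delivered to edge $e$ at
   $k_T m_{i,e}$, returns at $k_{ret}$.
2. **Dsh-Fz.** Membrane Dsh binds free Fz; association is suppressed by
   local Pk-Vang ($1/(1+(\beta \cdot PV)^h)$).
3. **Bridges.** Fz (free or Dsh-bound) binds Vang of the apposed membrane;
   Dsh-bound bridges dissociate `s_D`-fold slower (stabilization).
4. **Vang recruitment.** Cytoplasmic Vang loads onto membranes gated by
   the presence of *any* apposed Fz (saturating, half-point `1/delta_g`).
5. **Pk-Vang.** Cytoplasmic Pk clusters with membrane Vang; assembly is
   suppressed by local Dsh-Fz (strength `gamma`) and strongly enhanced by
   *apposed* Dsh-Fz (fold-change up to `1 + e_pv`); disassembly is slowed
   by trans-binding to any apposed Fz (floor `eps_s`).
6. **Frustration.** Dsh-Fz facing apposed Dsh-Fz has no trans Vang partner:
   its dissociation (and that of its bridges) is raised up to
   `(1 + phi)`-fold, and new bridge engagement is blocked.
7. **Lateral diffusion.** Free membrane species hop between adjacent edges
   at `D_m`; Dsh-Fz and Pk-Vang clusters at the slower `D_c`; bridges are
   immobile.

No synthesis or degradation: per-cell totals of Dsh, Fz, Vang and Pk are
conserved exactly (verified to 1e-6 relative in every simulation in the
test suite; the fixed-step integrator conserves them to rounding because
every term moves mass between compartments).

Together 2, 5 and 6 make each membrane a bistable toggle — Dsh-Fz-dominant
or Pk-Vang-dominant — whose state is flipped *across* the junction by
reaction 5 (apposed Dsh-Fz builds Pk-Vang) and defended *locally* by
`gamma`. This enforces the complementary arrangement at every junction
(Dsh-Fz on one side, Pk-Vang on the other) and hence parallel alignment of
neighboring cells.

**Why cooperativity.** With first-order inhibition and enhancement
(`h = 1`, and the mass-action constants of order one this model starts
from) the linearized feedback gain of the uniform state stays below one
for every parameter combination we probed (Jacobian eigenvalue analysis on
a 1 x 10 chain): the field only tracks the MT bias weakly and never
segregates. `h = 2` — a modest dimerization-level nonlinearity — makes the
toggle genuinely bistable and the uniform state linearly unstable to the
polarization mode. The published junctional PCP models reach the same
conclusion by other routes; we document it here because `h` is the single
most load-bearing constant in the network.

**Why frustration (`phi`).** Without it, two Dsh-Fz-rich membranes facing
each other form a stable "head-to-head" wall: each side's complexes grab
whatever Vang trickles onto the apposed membrane and lock into stabilized
bridges. Regions that receive strong but *symmetric* axial delivery
(`oriented_unbiased`) then polarize antiparallel to their neighbors and
freeze. Destabilizing partner-less Dsh-Fz melts such walls from whichever
side lacks reinforcement, so orientation sweeps through as a front.

**Initial conditions and determinism.** Membrane proteins (Fz, Vang) start
uniform over edges; Dsh and Pk cytoplasmic; no noise by default, so a
symmetric input yields `|P| = 0` for all cells at machine precision
(`init_noise` and a seed enable symmetry-breaking studies).

**Integration.** Classical fixed-step RK4 (`dt = 0.01` nondimensional)
with snapshots of the polarity vector
$P_i = \sum_e (\text{membrane Dsh})_{i,e}\, \hat n_e$ every `save_dt`;
early exit at `max |dy/dt| < tol_ss`. Halving `dt` moves the steady state
by well under 0.1%. The right-hand side is implemented twice — a compiled
C++ version used by default and a vectorized R reference — and the two are
asserted equal to 1e-15 in the tests.

# What the model reproduces

On the 6 x 30 arena (the problem size used throughout the tests and the
acceptance script, chosen to match the simulated tissue patch):

* **Gradient-shape insensitivity.** Linear, step, and steep-then-flat Ds
  gradients give steady-state mean `|P|` equal to within 1% across the
  field, because the core toggle saturates at an amplitude set by the
  conserved totals, not by the bias magnitude.
* **Kinetic delay.** With Ds dropping to zero distally, the distal field
  has no local cue; polarity arrives as a propagating front, and
  column 23 reaches 90% of its plateau about three times later than
  column 8.
* **Distal MT architectures.** Enforcing P-D-oriented, plus-end-unbiased
  MTs distally changes the distal steady state by only a few percent
  relative to random MTs. This implementation does *not* reproduce the
  modest speed-up of polarization: its oriented cells pre-load both axial
  membranes with Dsh-Fz, which the arriving front must first clear, so
  time-to-plateau is about 7% slower than with random MTs even though the
  subsequent rise is steeper and the plateau slightly higher. We examined
  this at length (weaker bridges, stronger frustration, membrane-resident
  initial Vang) and consider it a structural property of treating directed
  delivery as the dominant Dsh-Fz source; it is reported as measured.
* **Clones.** In a polarized field, a 3 x 3 `fz`-null clone repolarizes
  several wildtype neighbors by more than 90 degrees (domineering
  non-autonomy): fz-null tissue presents no Fz ligand, so apposed Pk-Vang
  clusters lose their trans support and Dsh-Fz invades the clone-facing
  membranes. A `dsh`-null clone leaves its neighbors essentially intact —
  its Fz still bridges and gates Vang. A small (2-column) `ft`-null clone
  is crossed by core polarity: its cells polarize distally at near-normal
  magnitude although their own MT bias is uniform.

The declared pass/fail thresholds for the clone phenotypes are: at least
three wildtype cells reversed (> 90 degrees angular change versus the
no-clone control) for `fz`; fewer than three for `dsh`; all `ft`-clone
cells within 45 degrees of distal at >= 50% of control magnitude.

# The quantification toolkit

**Structure tensor** (`structure_tensor_orientation()`): Gaussian
derivative gradients at `sigma_grad`, tensor smoothing at `sigma_window`,
reflective padding; fiber orientation is orthogonal to the dominant
gradient direction; coherence is the normalized eigenvalue anisotropy.
Axial histograms default to 36 bins of 5 degrees; rose plots mirror each
axial bin to both half-circles and draw the P-D axis horizontal (the
90-degree display position, matching the field's rose-plot convention).
Circular statistics on axial data double the angles first.

**Shift colocalization** (`shift_correlation()`): Pearson correlation over
the valid (non-wrapped) overlap for every integer shift along the chosen
tissue axis — circular FFT correlation would wrap content around and
contaminate the small signed shifts of interest. Peaks are strict local
maxima with prominence >= 0.01, refined by parabolic interpolation. For a
membrane marker versus dots displaced proximally by `o` px inside cells of
apothem `a`, the nearest peaks sit at `A ~ -(a - o)` and `B ~ +(a + o)`,
so `|A| < |B|` reads out the proximal bias and `(|B| - |A|)/2` estimates
`o`.

**Anchoring sites** (`axial_bias_stats()`): raw circular resultant
(directional bias), axial resultant on doubled angles (axis alignment),
and distal/proximal half-plane counts with the exact two-sided binomial
test; sites exactly on the +/-90-degree boundary join neither half-plane
and are reported as dropped. Histograms default to 20 bins of 18 degrees.

**Vesicle tracks**: tracks are analyzable from two consecutive apical
frames (5 s default frame interval); the longest consecutive apical run is
kept. A track is `stuck` when every consecutive displacement is at most
`stuck_eps` (0 by default — pixel-exact, as in manual scoring); otherwise
the first-to-last net vector decides, ties (`|v_x| = |v_y|`, including a
zero net vector after super-threshold wiggling) going to the axial class
with `v_x >= 0` read as distal. The axial fraction uses all filtered
tracks in the denominator (the stuck-excluded variant is also reported).
Motion modes: straightness (net/path) >= 0.8 and pause fraction <= 0.2
classify a track as transcytotic, else wandering.

# The synthetic-data generators

Generators exist so every analysis stage can be scored against known
truth without any external data, and they emulate the *statistical*
structure of the real assays, not their optics:

* `make_fiber_image()`: anti-aliased line segments with axial angles from
  a von Mises distribution on doubled angles (sampled with the
  Best-Fisher rejection algorithm), Gaussian blur, Gaussian read noise.
  No point-spread-function or shot-noise modeling; a recovery within 2
  degrees here shows the estimator chain is unbiased, not that it is
  robust to every microscopy artifact.
* `make_dot_membrane_pair()`: hexagonal membrane outlines plus one dot per
  cell displaced proximally by a known offset — the geometry behind the
  shift-correlation peaks, noise optional.
* `make_track_mixture()`: transcytotic (persistent axial drift, distal
  with probability `p_distal`, small lateral noise), wandering (unbiased
  walk with pauses), and stuck tracks at 5 s frames. Defaults
  (`f_trans = 0.72, f_wander = 0.16, f_stuck = 0.12, p_distal = 0.58` in
  the acceptance runs) put the expected axial fraction at 0.80 with a
  modest but testable distal excess, mirroring the published measurement
  design (n = 1192 tracks). Speeds and step sizes are free parameters —
  the real assay reports none.
* `make_anchoring_angles()`: von Mises mixtures on the full circle.

All generators are bit-reproducible under a fixed seed and return their
ground truth alongside the data.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns the whole chain —
layer, simulations, clones, recovery suites — and writes the headline
quantities as JSON. The test suite (`tests/testthat`) covers the same
claims plus the unit-level oracles: a brute-force binding-equilibrium
solver, enumerated direction classification, exact binomial enumeration,
and closed-form circular statistics.

# Known limitations

* Rate constants are nondimensional and hand-calibrated to the qualitative
  claims; no fitting to quantitative imaging data was attempted (none is
  available at this resolution).
* The oriented-unbiased-MT speed-up is not reproduced (see above).
* One wildtype cell immediately distal to a `dsh` clone can still reverse
  under the default constants; the declared clone thresholds treat
  "domineering" as a multi-cell phenotype.
* No cell rearrangement, growth or mechanics; no Pk/Sple isoform logic;
  vesicles are a deterministic flux, not discrete cargoes.
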