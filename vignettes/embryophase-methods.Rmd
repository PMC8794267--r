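---
title: "Phase-field modelling of the early C. elegans embryo: model, numerics and design choices"
author: "embryophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field modelling of the early C. elegans embryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Each cell *i* of the early embryo is represented by a smooth scalar field
`phi_i(r, t)` on a 3D lattice, with `phi = 1` inside the cell body, `phi = 0`
outside and the membrane identified with the 0.5 level set of the diffuse
interface.  A static field `phi_e` marks the eggshell (1 outside, 0 inside).
Four forces act on every cell field, each a line density supported on the
interface:

* **Surface tension** `F_ten = -gamma (lap(phi) - c W'(phi)) grad(phi)/|grad phi|^2`,
  the variational force of the Ginzburg–Landau surface energy with the
  double-well `W(phi) = phi^2 (phi - 1)^2`.  It drives cells toward spheres;
  `c` sets the interface (cortex) thickness, whose stationary 1D profile is
  `(1 + tanh(sqrt(c/2) x))/2` in lattice units.
* **Repulsion** `F_rep = (g_e phi phi_e^2 + g phi sum_j phi_j^2) grad(phi)/|grad phi|^2`,
  penalising overlap with the eggshell and with other cells.
* **Attraction** `F_atr = sum_j sigma_ij grad(phi_j)`, an advective pull
  along the neighbours' interface normals, with a symmetric per-pair
  coefficient matrix `sigma`.
* **Volume constraint** `F_vol = M (int phi - V(t)) grad(phi)/|grad phi|`
  (the gradient form of the inward-normal expression), holding each cell at
  its prescribed volume `V(t)`.

In the overdamped intracellular environment the force resultant balances
viscosity, giving the advective evolution
`d phi_i/dt = -(1/tau) (F_ten + F_rep + F_atr + F_vol) . grad(phi_i)`.

Cell division is an instantaneous bisection of the mother field by the plane
`n . (r - r_c) - b = 0` through the centre of mass: daughters are the mother
multiplied by the complementary sigmoids `(1 ± tanh((n.(r-r_c) - b)/eps))/2`,
so their sum reproduces the mother voxelwise.  The offset `b` is chosen so
the daughter-volume ratio matches the prescribed one, and the daughters'
prescribed volumes are the mother's split by the *achieved* mass fraction so
that the volume constraint does not fight the split.  With the default
`eps = 2^-52` the sigmoid saturates into a sharp `{0, 1/2, 1}` step mask.

Division timing is self-determined: the per-cell centroid velocities are
sampled, the embryo's root-mean-square velocity `vbar = sqrt(mean(v_i^2))`
is smoothed, and a *quasi-steady state* is a local minimum of `vbar(t)`
(first difference changes sign from − to +).  In the wild-type program the
6- and 7-cell stages end at their first quasi-steady state and the 8-cell
stage at its second; the pre-6-cell stages relax to mechanical equilibrium
under a velocity-floor rule.

## Reference parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `gamma` | surface tension strength | 0.25 | lattice |
| `c` | cortex thickness coefficient | 1 | lattice |
| `g_e` | eggshell stiffness | 16 | lattice |
| `g` | cell stiffness | 1.6 | lattice |
| `sigma_S`, `sigma_W`, `sigma'_S` | strong / weak / especially strong attraction | 0.9 / 0.2 / 1.6 | lattice |
| `M` | volume-constraint strength | 0.0012 | lattice (reference grid) |
| `tau` | viscosity | 2.62 | lattice |
| `h` | time step | 0.1 | time |
| `dl` | voxel pitch | 0.2508 | µm |
| `eps` | division interface width | 2^-52 | lattice |

The reference eggshell is a spheroid with semi-axes 27.5837 µm (A-P) and
18.3477 µm (D-V), compressed 16.7942 µm in total along L-R by slide
mounting, i.e. clipped at a half width of 9.9506 µm
(`halfWidthFromCompression(18.3477, 16.7942)`).  The uncompressed control
keeps the major axis and the enclosed volume and solves the minor semi-axis
from the closed-form clipped-spheroid volume.  The reference lattice is
256×128×256 voxels as (x, y, z): the short dimension carries the compressed
left-right axis, which is the only axis that fits in 128 × 0.2508 µm.

## Numerical scheme

* Second-order central differences; 7-point Laplacian; unit lattice spacing
  (`dl` enters only when reporting physical quantities and building
  geometry).  Replicate-edge (zero-gradient) boundaries: the eggshell keeps
  all cell mass several voxels away from the domain box, so the choice is
  inert.
* Explicit forward Euler with synchronous updates; a non-finite field value
  aborts with the offending step.  Interface motion per step is well below
  a voxel at the default parameters.
* The formal force expressions are 0/0 on flat regions; denominators are
  regularised with `gradEps = 1e-6` and forces are masked to the interface
  band `|grad phi|^2 > 1e-8`, consistent with their meaning as interface
  line densities.
* Fields are never clamped to [0, 1]; overshoot is monitored
  (`fieldHealth`) instead, preserving exact mass bookkeeping and the
  division-sum identity.
* The volume-force magnitude `M |int phi - V|` is capped (`volCap`,
  default 4).  The cap only engages far from the operating regime — chiefly
  while a freshly seeded zygote inflates from its initial sphere to the
  prescribed volume — and leaves equilibrium states untouched.
* The compute kernel restricts per-cell work to padded support bounding
  boxes refreshed every 50 steps; this is an exact optimisation (fields are
  zero outside their support up to 1e-7) verified against the full-domain
  force composition to machine precision.

## Event detection and the stage scheduler

Centroids are sampled every `sampleStride = 100` steps; `vbar` is smoothed
with a centred 21-sample moving average before minimum detection, and
detected minima must be separated by at least 20 samples.  These smoothing
parameters are this package's choices (the source curves are plotted
smoothed without stated parameters) and are configurable.  A minimum counts
as confirmed once it is at least half a smoothing window old; the stage
stops *at* the detected minimum's step, where the embryo is near
stationary.  The velocity-floor rule for pre-6-cell stages additionally
requires every cell's integrated volume to be within 10% of its prescribed
volume, so a symmetric, still-inflating cell (whose centroid does not move)
is not mistaken for equilibrium.  The floor itself is expressed in lattice
velocity units and scaled by `dl`; 1e-3·dl per time unit proved a robust
threshold across grid scales, sitting well above the centroid jitter floor
of coarse lattices.

## The attraction matrix

Attraction is binarized: sister pairs (same parent) get the weak level 0.2
— their shared membrane is freshly grown during cytokinesis, before
adhesive protein recovers — and non-sister pairs the strong level 0.9.
Single-pair overrides ("motifs") express measured deviations; the wild-type
8-cell stage uses the weak ABpl–E motif, and 1.6 encodes an especially
strong state (e.g. a strengthened ABpl–MS bond).  The matrix is dense: a
value exists for every pair and simply contributes no force without field
overlap (whether never-contacting pairs carry a value is unobservable).
The 1→4-cell stages follow the fitting narrative: no attraction below 4
cells, then the fitted 4-cell matrix (0.9 everywhere, 0.2 on EMS–P2); from
the 4→6 division onward the sister rule is regenerated after every division
and motifs are re-applied.

## Scenario library and placeholder inputs

`builtinScenario()` ships the wild-type compressed reference run, reduced
and uncompressed variants, the 4-cell attraction scans (global
σ ∈ {0, 0.3, 0.6, 0.9, 1.2, 1.5}; EMS–P2 ∈ {0, 0.2, 0.4, 0.6, 0.8}), a
17-motif 8-cell scan, a division-timing tree, the 3×3 P2
orientation/ratio grid, and two toy fixtures.  Several inputs that come
from measurements are **not** shipped and are replaced by flagged
placeholders (`provenance` in every config, surfaced on load):

* per-cell volumes: eggshell interior × packing fraction 0.75 (a real
  embryo occupies roughly three quarters of its eggshell), split
  AB:P1 = 55:45, EMS:P2 = 54:46, C:P3 = 2:1, other divisions symmetric;
* division orientations: ABa, ABp, EMS and P2 use the body-axis
  idealisations (D-V, L-R, A-P and D-V with the larger daughter C dorsal);
  the pre-4-cell orientations are geometric placeholders (P0 along A-P, AB
  and P1 tilted into the A-P/D-V plane so that ABp ends dorsal and P2
  posterior, reproducing the canonical 4-cell diamond).

Users with measured tables substitute them through the YAML config; the
loader logs every placeholder so no unsupported number enters a result
silently.

## Reduced grids

Reduced variants divide the linear resolution by `gridScale` and keep all
lattice-unit parameters except `M`, which is multiplied by `gridScale^3`:
prescribed volumes in lattice units shrink as `gridScale^-3`, so this keeps
the physical pressure scale `M (int phi - V)` invariant across resolutions
(at `gridScale = 1` it is exactly the reference value).  Without the
rescaling, coarse-grid cells equilibrate far below their prescribed
volumes.  Quantitative reproduction targets hold only at the reference
grid; reduced runs are for topology, ordering and direction-of-effect
questions.  At `gridScale = 8` (≈2 µm voxels) cells are 4–9 voxels in
radius: contact topologies and stage ordering are robust there, but
area-resolved comparisons and the subtle 8-cell motif phenotypes (ABpl
ingression versus anterior-ventral migration) are below the resolution —
the package computes and reports them at reduced scale without asserting
their direction.  The test suite runs single-cell and doublet checks at
~1 µm voxels (radius 8–15 voxel cells, 32³–48³ grids), the 4-cell and
8-cell topology programs at `gridScale = 8`, and one eggshell volume check
at the full reference lattice; these sizes are the package's chosen
compromise between discretisation error and turnaround.

## Morphometrics

* **Surface area**: `sum |grad phi| dl^2`, exact for a monotone 0→1
  interface profile; cross-checked by spherical ray quadrature of the 0.5
  isosurface (`surfaceArea(..., method = "ray")`).
* **Deformation** `alpha = ∮ (R - rbar)^2/(rbar^2 R^2) ds` over the
  `phi = 0.5` surface, with `rbar` the equal-volume sphere radius.  The
  surface integral is evaluated by ray casting from the centre of mass on a
  Fibonacci direction lattice with trilinear root refinement and an
  obliquity factor from the interpolated normal; this assumes star-shaped
  cells (true for the compact blobs the model produces) and is checked
  against dense parametric quadrature on ellipsoids.  A relaxed sphere
  gives `alpha < 1e-2`; `alpha` is scale-free.
* **Contact maps**: voxels are labelled by argmax over cells where the
  winning `phi > 0.5`; contact area is shared voxel faces × `dl^2`, and a
  pair "contacts" above a 1 µm² threshold (a few faces at reference
  resolution; the binarisation is this package's choice and configurable).
  Conserved-contact classification across replicate samples follows the
  all/none/intermediate rule; the deduplicated temporal sequence of contact
  maps is the developmental-path signature.
* **Planarization width**: the maximum pairwise distance in y among cell
  positions.  Field centroids stand in for the nuclei used experimentally —
  a documented discrepancy of a micrometre-scale offset at most.
* **Time-scale fit**: per-stage simulated durations (steps) are regressed
  through the origin on experimental durations (minutes) shifted by the
  fixed intercept `deltaT0 = 2.2784` min, the cytokinesis interval between
  nucleus separation and membrane segregation that the instantaneous
  bisection does not spend; `k` is steps per minute and intervals within a
  stage convert as `steps/k`.  The direction of the intercept (which axis
  carries `-deltaT0`) is ambiguous in the source description; this package
  subtracts it from the experimental minutes, matching the stated
  rationale.

## Known limitations

* No lamellipodia, protrusions or active contractility: the accelerated
  late-8-cell motion seen in vivo is intentionally outside the model.
* Stages beyond 8 cells, gradual cytokinesis and deformable eggshells are
  out of scope.
* The explicit scheme is only approximately variational: with attraction
  off, the discrete interface energy is non-increasing within a small
  per-step tolerance, not exactly.
* Placeholder volumes and pre-4-cell orientations (above) mean wild-type
  runs reproduce the canonical topologies, not measured per-embryo
  geometry; quantitative area tables require user-supplied measurements at
  the reference grid.

```{r example}
library(embryophase)
sc <- builtinScenario("wt_compressed_reduced", gridScale = 8)
res <- runScenario(sc, verbose = TRUE)
contactMap(res$embryo)
metricsReport(res$embryo)
```
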