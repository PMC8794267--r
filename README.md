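# embryophase

A 3D multicellular phase-field simulator for early *Caenorhabditis elegans*
embryogenesis (1- to 8-cell stages), with the morphometrics needed to
compare simulated embryos against imaging-derived measurements.

It is written for quantitative developmental biologists and biophysicists
who want to ask mechanistic questions — how division timing, division
orientation and the cell–cell adhesion pattern shape the stereotypic cell
arrangement of the early embryo — in a model where whole cell bodies,
shapes and contact interfaces are resolved, not just cell centres.

## The model

Each cell *i* is a smooth scalar field φᵢ(**r**, t) ∈ [0, 1] on a regular
lattice (membrane = the 0.5 level set); a static field φₑ marks the rigid,
optionally slide-compressed eggshell.  Cells evolve by overdamped advection

∂φᵢ/∂t = −(1/τ) (**F**_ten + **F**_rep + **F**_atr + **F**_vol) · ∇φᵢ,

with interface line-density forces

- **F**_ten = −γ(Δφᵢ − cW′(φᵢ)) ∇φᵢ/|∇φᵢ|², W(φ) = φ²(φ−1)² (surface tension),
- **F**_rep = (gₑ φᵢ φₑ² + g φᵢ Σ_{j≠i} φⱼ²) ∇φᵢ/|∇φᵢ)² (eggshell and cell repulsion),
- **F**_atr = Σ_{j≠i} σᵢⱼ ∇φⱼ (pairwise adhesion; binarized σ: 0.2 sisters, 0.9 non-sisters, 1.6 especially strong),
- **F**_vol = M(∫φᵢ d**r** − Vᵢ(t)) ∇φᵢ/|∇φᵢ| (volume constraint).

Cell division is an instantaneous bisection of the mother field by a plane
with prescribed orientation and daughter-volume ratio; division is
triggered when the embryo's root-mean-square cell speed v̄(t) reaches a
local minimum (a *quasi-steady state*).  The package ships the staged
wild-type program (1→2→3→4→6→7→8 cells), attraction/orientation/timing
scan scenarios, and metrics: surface and contact areas, ternary
conserved-contact classification, deformation coefficient α,
developmental-path signatures, left-right planarization width, and the
proportional fit converting simulation steps to minutes.

## Worked example

A coarse-grid (≈2 µm voxels) wild-type run from zygote to the 8-cell
stage, with the weak ABpl–E adhesion motif:

```r
library(embryophase)
sc  <- builtinScenario("wt_compressed_reduced", gridScale = 8)
res <- runScenario(sc)

res$durations
#> [1]  100  300 2300 2800 3400 2700 4300
contactMap(res$embryo)
#> ContactMap: 8 cells, 16 contacting pair(s) (threshold 1 um^2)
#>  cellA cellB      area
#>   ABal  ABar 140.89743
#>   ABal  ABpl 100.64102
#>   ...
contactArea(res$embryo, "ABpr", "MS")
#> [1] 56.35897
embryoWidth(res$embryo)
#> [1] 6.65198
```

`res$durations` are the per-stage durations in time steps — the 6/7-cell
stages end at their first velocity minimum and the 8-cell stage at its
second; they feed `fitTimescale()` to express simulated dynamics in
minutes.  The contact map shows the 8-cell adjacency (areas in µm²);
`ABpr–MS > 0` is one of the conserved contacts of the 8-cell stage, and
the embryo width along the compressed left-right axis is the
planarization metric.  The quantitative reference configuration is
`builtinScenario("wt_compressed_full")` (256×128×256 voxels at
0.2508 µm); coarse grids are for topology and direction-of-effect
questions (see the methods vignette, `vignettes/embryophase-methods.Rmd`).

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/embryophase.R", package="embryophase"))') \
    scenarios export wt_compressed_reduced scn.yaml 8
Rscript .../embryophase.R simulate --config scn.yaml --out run/
Rscript .../embryophase.R analyze --run run/
```

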