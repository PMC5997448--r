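# chiratube

A cell-based 3D vertex model of epithelial tube twisting driven by
intrinsic cell chirality.

## The problem

During *Drosophila* embryogenesis the hindgut — an epithelial tube —
rotates 90° anticlockwise. Before rotation its cells adopt a transiently
chiral, leftward-tilted shape; the rotation proceeds as that chirality
dissolves, with cells sliding directionally past their
anterior-posterior neighbors while keeping their junctions ("chiral cell
sliding"), rather than by cell intercalation. `chiratube` implements the
simulation half of that argument for tissue-mechanics researchers: a
vertex model of a closed polygonal tube whose cells are given chiral
shapes and then released, so that the sufficiency of cell-shape chirality
for directional tube twisting can be tested in silico, together with all
the quantification used to compare the model with live imaging.

## The model

The tube surface is a closed polygonal mesh (452 lateral cells + 2 caps,
904 vertices at full size), built by periodic Voronoi tessellation of a
random hard-disc packing in a 15.75 × 28.7 rectangle wrapped onto a
cylinder of diameter 5. Vertices obey overdamped gradient dynamics

    η dr_i/dt = −∇_i U,   U = U_L + U_ES + U_EV + U_B

with edge energy U_L = σ_L Σ_α Σ_k w_αk L_αk, cell-area elasticity
U_ES = κ_S Σ_α (S_α − S_o)², tube-volume elasticity
U_EV = κ_V (V − V_o)², and an end-ring restriction
U_B = κ_B Σ_j [(r_j − r_ring)² − R²]², integrated by fixed-step RK4
(h = 0.005) with T1 vertex reconnection when an edge becomes shorter than
δ = 0.3. Standard parameters: σ_L = 2.2, κ_S = 10, κ_V = 0.2, κ_B = 1,
S_o = 1, V_o = 566.64, ring radii 2.5.

Cell chirality is imprinted by polarity-directed anisotropic edge
contraction: each cell's two edges crossed by the plane perpendicular to
its polarity (deflected +30° from the tube axis for wild type, −35° for
the enantiomorphic variant) carry weight w = 3.5 while the dynamics run
to t = 5 (wild type) or t = 10 (inverted); the clock is then reset and
all weights return to 1. The subsequent relaxation twists the tube —
left-handed (positive) for wild type — while the cell-shape chirality
dissolves. See the methods vignette
(`vignettes/chiral-tube-twisting.Rmd`) for the full model description,
measurement conventions and design decisions.

## A worked example

```r
library(chiratube)

res <- run_experiment("wildtype", seed = 1, t_end = 80)
tail(res$twist, 3)
#>        t    twist
#> 159 79.0 42.68741
#> 160 79.5 42.76461
#> 161 80.0 42.84135
res$intercalations
#> $n_events
#> [1] 64
#>
#> $fraction
#> [1] 0.1415929

ss <- shape_stats(res$mesh0)        # the chiral t = 0 state
angle_histogram(ss$edge_angles)$bias
#> [1] 0.3160967
```

The twist trace gives the tube's accumulated twist angle in degrees
(positive = left-handed screw, the wild-type direction); here the tube
has twisted 42.8° by t = 80, driven by the dissolution of the imprinted
chirality — the edge-angle bias of +0.32 at t = 0 (edges slanting
leftward far more often than rightward) decays to near zero during the
run. `res$intercalations` counts T1 reconnection events: junction
remodeling stays rare, and the `no_reconnect` preset twists almost as far
with remodeling disabled, reproducing the argument that cell sliding, not
intercalation, drives the rotation. The `inverted` preset (mirror-image
chirality) twists the opposite way, and `fixed_ends` (end rings unable to
rotate) abolishes the twist while the cell chirality still dissolves.

A thin command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "chiratube", package = "chiratube"))')" \
    run --preset wildtype --seed 1 --t-end 80 --out out_wt
```

writing `trace.csv`, `events.csv`, shape/sliding/tilt tables, OBJ/JSON
meshes and the configuration (with hash) for exact replay.

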