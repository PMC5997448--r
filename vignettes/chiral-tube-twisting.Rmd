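---
title: "A cell-based vertex model of chirality-driven epithelial tube twisting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-based vertex model of chirality-driven epithelial tube twisting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`chiratube` simulates an epithelial tube — a curved sheet of polygonal
cells closed by two end caps — whose cells carry an intrinsic left-right
asymmetry (cell chirality), and quantifies how the dissolution of that
chirality twists the whole tube. The motivating system is the embryonic
*Drosophila* hindgut, which rotates 90° anticlockwise as its epithelial
cells lose a transient leftward tilt; cells slide past their
anterior-posterior neighbors without exchanging junction partners
("chiral cell sliding").

The tissue is a single curved polygonal sheet in 3D: 452 lateral cells
plus two cap faces at full size, with every vertex shared by exactly three
faces. Vertices move by overdamped gradient descent,

$$\eta\,\frac{d\mathbf r_i}{dt} = -\nabla_i U, \qquad i = 1,\dots,n_v ,$$

so the potential never increases along a trajectory. After rescaling
lengths by the relaxed cell size $R_o = S_o^{1/2}$ and time by
$1/(\eta R_o)$, the drag coefficient disappears and the potential is

$$U = U_L + U_{ES} + U_{EV} + U_B$$

with

* **edge energy** $U_L = \sigma_L \sum_\alpha \sum_k w_{\alpha k}
  L_{\alpha k}$ — summed over every cell $\alpha$ and its edges, so an
  interior edge is counted through both incident cells (this literal
  per-cell reading is the default; `model_params(edge_count =
  "per_edge")` switches to counting each physical boundary once). The
  weight $w_{\alpha k}$ is 1 except on "special" edges during chirality
  induction;
* **area elasticity** $U_{ES} = \kappa_S \sum_\alpha (S_\alpha - S_o)^2$
  over the lateral cells, with the area of a (generally non-planar) face
  defined by centroid-fan triangulation;
* **volume elasticity** $U_{EV} = \kappa_V (V - V_o)^2$ for the enclosed
  tube volume (divergence theorem over all faces, caps included);
* **end-ring restriction** $U_B = \kappa_B \sum_{j \in \mathrm{ring}}
  \left[(\mathbf r_j - \mathbf r_{\mathrm{ring}})^2 - R^2\right]^2$ for
  both rings, with $\mathbf r_{\mathrm{ring}}$ the instantaneous ring
  centroid. The printed formula alone restricts ring vertices to spheres;
  to realize the intended *circles* the z coordinate of ring vertices is
  additionally held at its initial value. (Releasing z was tried: the
  tube then shortens by roughly a quarter of its height during
  relaxation, contradicting the fixed tube proportions, so the frozen-z
  variant is the default, switchable via `model_params(fix_ring_z =
  FALSE)`.)

Integration is classical fixed-step 4th-order Runge-Kutta with
$h = 0.005$. The standard parameters are $\sigma_L = 2.2$,
$\kappa_S = 10$, $\kappa_V = 0.2$, $\kappa_B = 1$, $S_o = 1$,
$V_o = 566.64$, ring radii 2.5.

## Tube construction

The initial condition is a periodic Voronoi tessellation: 452 disc
centres of hard-core diameter 0.82 are placed by random sequential
adsorption in a 15.75 × 28.7 rectangle, periodic in the width direction
(the eventual circumference), then tessellated. This packing sits close
to the 2D adsorption jamming density, so placement uses a grid-accelerated
sampler with an explicit attempt budget (10^6). Voronoi cells are computed
by half-plane clipping against nearby seed images; shared vertices are
identified *topologically* (by the set of seeds/boundary lines defining
each vertex), so adjacent cells reference identical coordinates and the
cell areas tile the rectangle to machine precision. The rectangle is
wrapped onto a cylinder ($\phi = 2\pi x / W$, radius `diameter/2`, height
$\to z$), and the two rows of boundary vertices become the end rings and
cap faces of a closed, outward-oriented surface with $V - E + F = 2$ and
$n_v = 2 \times 452 = 904$.

The width 15.75 is taken verbatim even though $\pi \cdot 5.0 \approx
15.708$: the wrap uses the rectangle width as the exact circumference,
and the nominal diameter 5.0 enters only through the ring radii and the
analysis projection, so both printed numbers are honored.

A random Voronoi tessellation generically contains very short edges
(near-degenerate fourfold configurations). These are genuine features of
the geometry, not artifacts; the numerical policies below are designed
around them.

## Chirality induction

Each lateral cell receives a unit polarity vector in its local tangent
plane, deflected from the anterior-posterior (+z) axis by +30° (wild
type) or −35° (inverted). The plane through the cell centroid
perpendicular to the polarity crosses exactly two edges of the (convex)
cell; these "special" edges receive weight $w = 3.5$ and contract
strongly while the dynamics run to $t = 5$ (wild type) or $t = 10$
(inverted). Cells elongate along their polarity and acquire a chiral
shape; the clock is then reset and all weights return to 1.

Orientation contract: positive deflection tilts polarity toward
decreasing azimuth, which is *leftward* when the tube is viewed from
outside with anterior up. On the unrolled analysis plane
($x = \phi \cdot$ radius, $y = z$), leftward is $-x$; cell-axis and edge
angles are measured from the axial direction, positive toward $+x$ and
folded into $(-90°, 90°]$, so wild-type induction gives negative mean
angles and a positive leftward bias statistic (fraction of angles in
$(-90°, 0°)$ minus fraction in $(0°, 90°)$). Twist is measured with
azimuth taken counter-clockwise viewed from the posterior end, so the
wild-type left-handed screw is positive and a synthetic helical map
$\phi' \mathrel{+}= c\,z$ measures exactly $c \cdot (z_{top} -
z_{bottom})$.

Three pipeline choices were genuinely open and were settled by
experiment; each is recorded here as the package's design:

* **Pre-relaxation.** The raw wrapped tessellation is first relaxed with
  isotropic weights ($t = 5$, reconnection on) to the stable tube shape
  before polarity is assigned. Inducing chirality on the unrelaxed mesh
  contaminates the stored chirality with ordinary packing relaxation and
  visibly degrades the early twist dynamics.
* **No junction remodeling during induction.** With reconnection enabled
  during the anisotropic-contraction phase, every contracted special edge
  is consumed by a neighbor exchange shortly after crossing the critical
  length, the t = 0 edge-angle distribution loses nearly all of its
  leftward bias, and the subsequent relaxation twists with the wrong
  handedness. The contracted special edges *are* the stored chirality:
  they must survive induction. Induction therefore runs without
  reconnection (`build_chiral_tube(reconnect = FALSE)` default).
* **No re-selection of destroyed special edges.** If a reconnection does
  destroy a special edge (possible when induction is run with
  reconnection enabled), re-selecting a replacement from the current
  geometry creates a treadmill — every swap spawns a fresh strongly
  contracting edge — that produces thousands of events and eventually a
  numerical blow-up. By default a destroyed special edge is simply
  dropped (`reselect = TRUE` restores the other behavior).

## Reconnection (T1) rules

When an interior edge (no endpoint on an end ring) *becomes* shorter than
$\delta = 0.3$ — a downward crossing during the dynamics — the standard
T1 neighbor exchange runs: the two flanking faces lose the edge, the two
side faces gain it, and the two vertices are repositioned perpendicular
to the old edge within the local tangent plane, separated by
$1.05\,\delta$ so the new edge immediately exceeds the threshold.
Numerical policies:

* **Crossing semantics with hysteresis.** An edge that is already below
  $\delta$ at the start of a run, that was just created by a T1, or whose
  swap was refused, is *disarmed*: it cannot trigger until it has regrown
  past $1.5\,\delta$. Without this rule the short edges intrinsic to the
  initial Voronoi geometry fire an avalanche at $t = 0$, and
  energetically frustrated configurations toggle indefinitely.
* **Guards.** A swap is refused (and logged) when a flanking face would
  drop below 3 sides, when the four involved faces are not distinct, or
  when any involved face is degenerate (area below $0.05\,S_o$) —
  repositioning two vertices $1.05\,\delta$ apart inside a collapsed
  cluster tangles the face loops and destabilizes the integration.
* Checks run before every RK4 step; multiple sub-threshold edges are
  processed in ascending length order.

During induction a few cells whose boundary is dominated by special edges
(their own plus their neighbors') can collapse to near-zero area. The
collapsed clusters are harmless to the integration (edge forces have
constant magnitude) and partially re-inflate during relaxation; the
degenerate-face guard keeps reconnections away from them.

## Quantification

* **Twist angle** — per-vertex azimuth change relative to t = 0,
  averaged over the top ring minus the bottom ring, unwrapped along the
  saved trajectory. A regression variant (slope of azimuth change against
  z times tube height) is provided as a cross-check.
* **Cell shape** — polygons are projected radially onto the nominal
  cylinder (diameter 5.0) and unrolled; each polygon is approximated by
  its momental ellipse (second area moments about the centroid). The
  major-axis direction is the cell axis; the deviation from a circle is
  $(d_{max} - d_{min}) / (d_{max} + d_{min})$. A 2:1 rectangle has
  deviation exactly 1/3; a near-circular polygon reports angle 0 by the
  tie rule. Cells within two rows of either end are excluded from shape
  statistics.
* **Cell sliding** — for every axially adjacent (upper, subjacent) cell
  pair, the subjacent centroid is the origin and the relative
  circumferential displacement of the upper cell is measured; negative is
  leftward, the wild-type direction.
* **Boundary tilting** — the angle change of the shared boundary of each
  column pair, classified counter-clockwise / unchanged / clockwise with
  a 2° tolerance (the source quantification prints no threshold; 2° is
  the package default).
* **Intercalation** — column pairs that lose contact and acquire an
  intervening cell adjacent to both, with the side the intervening cell
  came from; reconnection events are also logged directly by the
  simulator.

## What the generator emulates — and what it does not

The synthetic tube is the study system itself: the tessellation
reproduces the published construction (cell number, rectangle, disc
diameter, wrap). It does *not* emulate real hindgut features absent from
the model: anterior-posterior elongation (convergent extension), cell
division or extrusion, apical-basal structure, or molecular polarity
dynamics — polarity is an imposed field. Passing tests therefore
demonstrate the mechanical sufficiency argument (chiral cell shape →
directional twisting via cell sliding) within this model, not a
quantitative prediction for embryos.

## Known limitations

* With every printed parameter honored, the relaxation twist in this
  implementation is the near-complete recovery of the twist stored
  during the induction phase, and reaches roughly half the published
  wild-type value at t = 80 (the acceptance script prints the exact
  numbers it computes). The early-phase twist (t = 1) and every
  direction/handedness result — inverted protocol, mirror equivariance,
  no-reconnection control, fixed-ends control, sliding and boundary-tilt
  directions — match the published behavior. The reference study's
  post-reconnection vertex geometry, exact polygon-area definition and
  particular random initial tube were never published; those details
  bound what can be reproduced exactly.
* Reconnection events during relaxation are several-fold more frequent
  here than the published count (tens rather than ~12 per run); the
  crossing-with-hysteresis trigger already suppresses re-fires, so the
  residual excess likely traces to the same unpublished details.
* Vertices are assumed 3-valent throughout (guaranteed by the Voronoi
  construction and preserved by T1); fourfold degeneracies are not
  resolved explicitly but persist as disarmed short edges.

## Problem sizes used by the test suite

Module and property tests run on miniature tubes (16-60 cells, mean cell
area 1, targets rescaled to the fixture's own initial volume and areas)
and finish in seconds. The acceptance checks run the full 452-cell
pipeline: five packing seeds for the wild-type experiment (t = 100,
20,000 steps each), plus no-reconnection, inverted and fixed-ends
variants on a subset of seeds.

## A minimal session

```{r, eval = FALSE}
library(chiratube)

# full pipeline, one seed
res <- run_experiment("wildtype", seed = 1, t_end = 80)
tail(res$twist, 1)                      # twist angle at t = 80
res$intercalations                      # reconnection count and fraction

# stage by stage
tess <- generate_initial_tessellation(seed = 1)
tube <- wrap_to_cylinder(tess)
pre  <- run_dynamics(tube, model_params(), t_end = 5)
chir <- build_chiral_tube(pre$mesh, chirality_protocol("wildtype"))
traj <- run_dynamics(chir$mesh, model_params(), t_end = 80)
twist_trace(traj)
shape_stats(traj$mesh)
```
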