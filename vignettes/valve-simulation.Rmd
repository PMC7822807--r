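---
title: "Simulating mitral valve closure with an editable cord model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mitral valve closure with an editable cord model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitralsim` simulates the opening and closing of the mitral valve as a
constrained thin shell: the leaflet surface is a triangle mesh evolved by
extended position-based dynamics (XPBD), the annulus ring and the papillary
muscle tips are prescribed (Dirichlet) boundaries, and the chordae tendineae
— invisible in echocardiographic images and therefore unknown — are supplied
by a heuristic model that the user can refine interactively. This vignette
documents the model, its parameters, the synthetic fixtures, and the
numerical choices, in that order.

## The leaflet model

The open-state valve is a triangulated surface with per-vertex leaflet labels
(anterior/posterior), an ordered annulus ring and an ordered free-edge
(orifice) polyline. From the initial geometry, `build_constraints()` derives

* one **distance constraint** per unique mesh edge, `C = |p_i − p_j| − l₀`,
  with the rest length set to the initial edge length — the membrane
  response;
* one **bending constraint** per interior edge, `C = φ − φ₀` on the dihedral
  angle between the two incident triangles (flat = π), with the standard
  four-point gradient obtained by differentiating through both face normals;
* one **area constraint** per triangle, `C = A − A₀`, which together conserve
  the total leaflet surface area.

Each constraint carries an XPBD compliance `α` (inverse stiffness; `α = 0`
is a hard constraint). One projection updates the accumulated multiplier by
`Δλ = (−C − α̃λ) / (Σ w‖∇C‖² + α̃)` with `α̃ = α/Δt²`, and moves each vertex by
`w ∇C Δλ`; vertices with inverse mass `w = 0` never move. Contact between
leaflets is handled by transient one-sided vertex–triangle constraints
(`C = dist − h ≥ 0`, thickness `h = 0.5` mm), regenerated every substep from
a uniform spatial hash; coaptation arises purely from these contacts, never
from shared mesh vertices. Cord constraints (below) are one-sided in the
opposite direction: they resist stretch only.

Material defaults (`material_params()`): distance compliance `1e-8`
(practically inextensible), area `0` (areas are conserved exactly up to
solver residual), bending `3e-4`. The bending value is deliberately soft:
leaflet tissue bends far more easily than it stretches, and the funnel-shaped
open leaflet must evert into a dome during closure. Substantially stiffer
bending (below ~`1e-4`) freezes the open shape and the valve never coapts;
the default leaves a wide margin on the fixture.

## Forces and boundary conditions

The blood is not simulated. Its action is reduced to two fields
(`force_phase()`):

```
f_i = s · P · A_i · n_i  +  γ · m_i · (s · v_t · (−n_AP) − v_i)
```

a pressure `P` acting along the area-weighted vertex normal `n_i` (lumped
area `A_i` = one third of the incident triangle areas), and a linear drag of
gain `γ` toward a uniform target flow of speed `v_t` along the annulus-plane
normal `n_AP`. The phase sign `s` is `+1` during closing (systole) and `−1`
during opening; switching phase (`switch_phase()`) only flips `s`. With the
sign convention above, a *negative* `v_t` makes the closing-phase flow run
from ventricle to atrium — the direction that carries the leaflets toward
closure — and the presets use `P = 1500`, `γ = 20 s⁻¹`, `v_t = −40 mm/s`
(model units: masses are 1 per vertex, so pressure is acceleration per mm²).
These magnitudes were calibrated once on the synthetic fixture so that the
competent preset closes and coapts; they are configuration, not physiology.

The annulus plane is fit by PCA of the annulus contour (smallest-eigenvalue
eigenvector), then oriented so the free edge lies on the ventricular
(negative) side. The annulus ring itself is a Dirichlet boundary interpolated
linearly between the open contour (t = 0) and the closed contour over
`close_duration` (0.25 s by default), clamped afterwards; when the two
contours have different point counts the closed one is resampled by arc
length and cyclically aligned, but a matching count is taken as an explicit
correspondence and used verbatim. Linear interpolation was chosen as the
simplest schedule; it is a parameter of `annulus_contour()` inputs, not of
the solver.

## The cord model

Cords connect a leaflet vertex `v` to one of two papillary tips. Each cord is
a distance constraint weighted by the tension switch

```
k = 0   if |p_v − p_tip| − l₀ < 0   (compression: the vertex moves freely)
k = 1   if |p_v − p_tip| − l₀ ≥ 0   (stretch: the constraint acts)
```

with the boundary case counted as stretch. With compliance `α = 0` (rigid
mode, the default) a cord cannot extend past `l₀` but exerts no force
otherwise; elastic mode sets `α = 1/E` per cord class with user-supplied
Young's moduli (literature values differ for primary and secondary cords, so
no default is shipped).

When the papillary muscles cannot be identified in images, the two tips are
placed heuristically: the cord attachment vertices are split into two lateral
subsets (each mixing anterior and posterior vertices), and for each subset
with centroid `c` at unsigned plane distance `d`, the tip is `c − d·n_AP` —
the centroid reflected through its own plane distance, deeper into the
ventricle, so the tip's plane distance is exactly `2d`. Heuristic tips are
static; manually supplied tips may be keyed open/closed and are interpolated
with the annulus schedule. Initial rest lengths are
`l₀ = dist(v, plane) + dist(v, tip)`, both unsigned: a vertex sitting at the
subset centroid is thereby bound exactly to the annulus plane in the closed
state, and vertices elsewhere get proportionally more headroom. Cords
attached within one edge-ring of the free edge are *primary*, the rest
*secondary* (the ring radius is a parameter; "close to the orifice" is
inherently qualitative).

The editor (`edit_command()` / `apply_edit()` / `run_session()`) scales rest
lengths multiplicatively at three granularities — one cord, one of the four
anatomical groups, or all cords — and may do so between solver steps without
any state reset; an absolute-set variant exists for reproducibility. A
session script is the headless substitute for the original interactive
workflow; after each command a deviation/prolapse snapshot is recorded.

## Time stepping

Each step of `Δt = 1 ms` runs 4 substeps of: (1) write the Dirichlet
positions for the substep's end time; (2) semi-implicit Euler predictor under
the external forces; (3) reset all multipliers, detect collisions, and run 20
nonlinear Gauss–Seidel sweeps over distance → bending → area → cords →
contacts, each family in a fixed deterministic order; (4) velocity update
`(p_new − p_old)/Δt` scaled by the per-step damping 0.1 (applied as an
equivalent per-substep factor). Steady state is declared when the maximum
per-vertex displacement per step stays below `2e-4` mm for 25 consecutive
steps; a step cap (default 4000) turns a non-converging run into a flagged
result, not an error. Everything is single-threaded and order-deterministic:
identical inputs give bit-identical trajectories.

**Mirror equivariance.** For scenes whose mesh is left–right symmetric the
solver processes constraints in mirror pairs: both members of a pair are
projected from the same state and their corrections applied together. For
vertex-disjoint pairs this is bit-identical to sequential Gauss–Seidel, and
for pairs sharing a midline vertex it makes the sweep exactly
mirror-equivariant, so closure trajectories remain symmetric to rounding
accuracy for as long as the dynamics themselves are stable (see
Limitations).

## The synthetic valve

`generate_scene()` builds a stylized valve from typical adult dimensions:
elliptical annulus with semi-axes 17 × 13 mm and a `cos 2θ` saddle of 1.5 mm
amplitude; two ruled leaflet sheets hanging 14 mm into the ventricle and
tapering to a free edge at 35 % of the annulus radius; anterior sector 45 %
of the circumference. The anterior leaflet is 1.15× deeper and the posterior
0.8× — as in the heart — which also places the coaptation line posteriorly
so the free edges shingle into overlap instead of meeting tip-to-tip (a
symmetric-depth valve deadlocks edge-against-edge). The closed annulus is a
96 % in-plane contraction of the open ring. Leaflets are separate meshes,
inset half a column from the commissures. Cord attachments cover the free
edge (primary) and every belly ring from 40 % depth outward (secondary),
split into lateral halves; midline vertices cord to both tips. Raw heuristic
rest lengths leave about +2.3 mm of closed-state headroom on this geometry,
so the generator applies a global `cord_tension = 0.92` — the synthetic
analogue of the manual refinement the heuristic is known to need — putting
competent closure at ~0.25 mm above the plane, well under the 2 mm prolapse
threshold.

Presets: `competent`; `prolapse_posterior` (posterior–posteromedial cords
elongated ×1.6, closing to a ~6 mm posterior prolapse); `ruptured_cord` (two
primary cords removed). Scaling the elongated group back by 1/1.6 through the
editor restores a competent closure and strictly reduces the deviation to the
competent preset's reference tracings. Mesh generation is fully
deterministic; the only randomness anywhere is the isotropic noise added by
`generate_reference_tracings()`, which slices the (closed) surface with
parallel image-like planes and chains the intersection segments into
polylines.

What the fixture does *not* emulate: real TEE reconstructions have irregular
annuli, scalloped leaflets (A1–A3/P1–P3), spatially varying thickness and
segmentation noise. Passing fixtures therefore demonstrates the solver and
cord machinery, not image-derived accuracy.

## Evaluation

`evaluate_deviation()` reproduces the closed-valve scoring geometry:
tracing polylines are resampled at 0.5 mm arc length, each sample's exact
minimum distance to the deformed surface is computed (vertex/edge/face cases,
accelerated by an AABB tree that provably returns the brute-force minimum),
and the pooled distances are summarized as min / median / max / mean ± SD.
The direction is tracing → surface, not symmetric Hausdorff. The median of an
even pool is the average of the two central values, so reports are
bit-reproducible. `detect_prolapse()` measures signed heights of non-annulus
vertices above the best-fit plane of the *closed* annulus contour (a
simplification of the saddle ring), oriented to the atrial side, and flags
any vertex above 2 mm — the conventional clinical cut-off.

## Numerical choices and degenerate inputs

* Collinear or short contour inputs, empty cord subsets, non-manifold edges,
  zero-area triangles and out-of-range indices are rejected with named
  errors at construction time, not during the solve.
* A distance or cord constraint with coincident endpoints, a degenerate
  triangle, or an exactly flat hinge has no defined gradient; the projection
  skips such configurations instead of dividing by ~0.
* The collision hash uses a cell size of `max(h, mean triangle extent)`;
  detection results equal the brute-force all-pairs scan, only the candidate
  enumeration changes.
* Problem sizes used throughout the tests and the acceptance script: the
  default fixture has ~320 vertices and ~220 cords, closes in ~700–900 steps,
  and one closure takes a few seconds of CPU; these sizes were chosen so the
  whole verification battery exercises every code path comfortably.

## Limitations

* **Lateral bistability of the coapted state.** A competent closure presses
  the shingled free-edge overlap together; that compressed arch can buckle
  left or right, and the perfectly symmetric configuration is an unstable
  equilibrium between the two. Even with the mirror-equivariant sweep, femto-
  scale rounding residues (e.g. from accumulation order in vertex normals)
  grow roughly like e^(0.05·step) once contacts are active, and a symmetric
  valve settles a few millimetres into one of the two mirror-image closed
  states. The choice of branch is deterministic — repeated runs are
  bit-identical — but not symmetric, and byte-level perturbations of the
  inputs (e.g. a 9-significant-digit file round trip) may select the other
  branch. Gentler closures (soft pre-contact regimes) remain symmetric to
  ~1e-8 mm.
* No fluid, no fluid–structure interaction, no anisotropic or nonlinear
  leaflet material, no cord branching or rupture dynamics (rupture is cord
  removal), no friction in contact.
* The prolapse reference is a plane, not the saddle ring; heights near the
  commissures are accordingly approximate.
* Force-field magnitudes are fixture calibrations exposed in configuration;
  they are not patient hemodynamics.
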