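---
title: "Modeling alveolar capillary unit perfusion and filtration from subpleural imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling alveolar capillary unit perfusion and filtration from subpleural imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 5)
library(acuflow)
```

## The problem

In the subpleural lung, each alveolar capillary unit (ACU) is fed by
distribution vessels (50–250 μm) that supply, in parallel, the **corner
vessels** running along alveolar edges (10–50 μm) and the **septal capillary
network** on the alveolar walls (5–8 μm). The septal mesh is the main
gas-exchange and fluid-filtration surface, but it cannot be imaged directly
through a pleural window; only distribution and corner vessels can. During an
edemagenic challenge such as alveolar hypoxia, sub-100-μm distribution vessels
constrict (to roughly half their baseline diameter around 30 min, with
reperfusion by 80–120 min), corner vessels respond mildly, and the
peri-microvascular interstitial pressure rises from about −10 cmH₂O toward
+3 cmH₂O as interstitial edema develops.

`acuflow` turns what *can* be measured — vessel diameters on greyscale images,
alveolar outlines, corner junction positions — into a quantitative model of
what cannot: septal perfusion, its partition against the corner pathway, and
Starling filtration across the septal walls. The chain is:

1. **segmentation** — vessel diameters from transect intensity profiles;
   interstitial area as ROI minus alveolar area;
2. **geometry** — a 2D ACU network built by Voronoi tessellation constrained
   to the corner-vessel polygon, with the interior point count calibrated to a
   morphological volume-ratio constraint;
3. **hemodynamics** — steady Poiseuille flow on the network under arteriolar,
   venular and interstitial pressure boundary conditions, with a
   transmural-pressure patency rule for septal capillaries;
4. **filtration** — Starling fluxes over the patent septal surface;
5. **pipeline** — the per-timepoint study (`run_study()`) producing a summary
   table of ACU flow, septal-to-corner flow ratio, filtration surface and
   surface-normalised filtration flow with percent changes versus baseline.

Because no imaging data ship with the package, a first-class synthetic-data
module generates ground-truthed images, alveolar fields, skeletons and
diameter time-courses; every downstream stage is tested against that ground
truth.

## Vessel segmentation

A vessel lumen images dark on a brighter parenchymal background. A transect
drawn perpendicular to the vessel axis is sampled by bilinear interpolation at
half-pixel steps; the profile is smoothed with a short moving average (default
3 samples), and the vessel border on each flank is the position of maximal
gradient magnitude between the profile's interior minimum and the surround,
refined to sub-sample precision by 3-point parabolic interpolation of the
gradient peak. This rule is affine-invariant in grey levels: scaling and
offsetting the image moves no border. A lumen is only accepted when the
interior minimum is darker than the flanking surround by a configurable
contrast threshold (default 15 grey levels); with 4 transects per vessel
(evenly spaced stations, the diameter is their arithmetic mean), a vessel is
declared closed when at least 3 of 4 transects find no lumen.

Against the synthetic generator's ground truth (widths 15–250 μm at
7.2 μm/pixel, optical blur of one pixel, texture noise), mean absolute
diameter error stays below one pixel — the acceptance suite checks exactly
this. Diameter classes (corner 10–50 μm, small distribution 50–100 μm, large
distribution 100–250 μm; boundaries to the larger class) are assigned from
the *baseline* diameter and kept through constriction, since the study tracks
the same vessels over time.

## Constrained Voronoi geometry and the 1.54 calibration

The corner skeleton is a closed polygon of corner vessels. The septal mesh is
modeled as the Voronoi diagram of N uniformly sampled interior points, clipped
to the polygon: interior ridges become septal edges (diameters i.i.d. uniform
on 5–8 μm), and ridge–boundary intersections subdivide the corner vessels,
joining the two meshes. The package computes clipped Voronoi cells directly by
incremental half-plane (perpendicular-bisector) intersection with
nearest-first pruning — each cell stops clipping once no farther generator can
cut it — which handles arbitrary simple polygons and needs no external
geometry stack. Vertices closer than 10⁻⁶ μm are merged; this tolerance is
seven orders of magnitude below any physical edge length and absorbs the
floating-point noise of recomputing a shared ridge vertex from two adjacent
cells' clip sequences (a much tighter merge radius risks double-counting a
ridge). For concave skeletons, clipping can leave zero-measure bridge segments
crossing a concavity notch; segments whose midpoints fall outside the polygon
are discarded and any orphaned vertices pruned. The planar subdivision is
checked by its Euler characteristic (V − E + F = 2) in the tests.

The model is 2D but the morphological constraint is volumetric: the fully
extended rabbit capillary network has a capillary-to-interstitial volume
ratio of 1.54. The 2D-to-volume bridge treats septal edges as cylinders
(volume `π/4·d²·L`) inside a barrier slab of thickness `t` over the ACU
polygon, so the interstitial volume is `area·t − V_capillary`. The thickness
`t` defaults to 6.5 μm, the mean septal diameter — the thinnest slab that can
contain the capillaries — and is exposed in the configuration because no
unique 2D-to-3D mapping exists. Corner and distribution vessels are excluded
from the ratio: the constraint describes the septal capillary network.

`calibrate_n_points()` exploits that the achieved ratio grows with N (total
ridge length scales like √N): it brackets exponentially, then binary-searches
the smallest N whose mean ratio over 5 seed replicates (common random numbers
across N) enters the 1.54 ± 0.05 band. For a hexagonal ACU with 273-μm mean
corner length this lands near N ≈ 600–650 and the achieved ratio within about
3% of the target; the acceptance script recomputes this from scratch.

## Perfusion with de-recruitment

Each patent edge has Hagen–Poiseuille conductance `g = π d⁴ / (128 μ L)`
(blood viscosity constant at 2×10⁻³ Pa·s; no diameter-dependent rheology).
Node pressures solve the weighted graph-Laplacian Dirichlet problem — P_art
at arteriolar access nodes, P_ven at venular exits (defaults follow the edema
time course: 16/16/16, 6/8/8, with P_i −10/−6/+3 cmH₂O at 0/30/120 min) —
via a sparse symmetric solve; patent components with no boundary contact are
stagnant at P_i. Septal patency is a binary transmural rule: an edge is open
iff the mean of its endpoint pressures exceeds P_i by more than a threshold
(default 0 cmH₂O). Corner vessels never close — parenchymal elastic tension
holds them open — and distribution vessels carry their closure in their
measured diameters. Pressures and patency are iterated from the all-patent
state to a fixed point; on a limit cycle the de-recruited reading is taken
(an edge stays open only if it was open in every state of the cycle), which
makes the result deterministic.

Two accounting choices deserve note. The ACU flow is the total flow leaving
the inlet nodes. The septal-to-corner partition is measured on the
**mid-pressure cut**: nodes are split at P\* = (P_art + P_ven)/2, every edge
crossing the cut carries flow from the high to the low side, and the kind-wise
cut flows are non-negative and sum exactly to the ACU flow. This makes the
reported ratio conservation-consistent, unlike summing |Q| over all edges of
a kind (which double-counts series segments).

A structural consequence of the binary rule is worth stating plainly: under
the default boundary table, luminal pressure is bounded below by P_ven
(6–8 cmH₂O), which exceeds every tabulated P_i (max +3 cmH₂O), so no septal
edge closes along the standard time course — de-recruitment begins only once
P_i enters the luminal range, and at P_i ≥ P_art the septal network closes
completely while flow persists through the corner pathway. A continuous
compliance law (vessel caliber shrinking with transmural pressure) would
de-recruit earlier and is the natural refinement; the binary threshold is the
minimal reading of "closure" and is exposed via `physio_params(p_close = )`.
For the same reason the surface-normalised filtration flow cannot rise
between baseline and the P_i = +3 timepoint in this surrogate — the effective
Starling gradient falls by ~13 cmH₂O while capillary pressure stays within
[P_ven, P_art] — so cross-network comparisons (which network shifts more) are
the meaningful output, not the sign of the shift.

## Starling filtration

Each patent septal edge filters according to
`Jv = Lp · S · [(Pc − P_i) − σ(π_c − π_i)]` with `S = π d L` the lateral
cylinder surface and `Pc` the mean of the edge's endpoint pressures. Negative
values mean re-absorption, as expected for unperfused or low-pressure
segments once interstitial pressure rises. The permeability parameters are
declared assumptions (the source imaging study uses but does not print them):
σ = 0.9, π_c − π_i = 15 cmH₂O (34 − 19), and Lp = 4×10⁻¹¹ m/(s·cmH₂O) chosen
once so that baseline Jv/S falls in the 10⁻¹⁰ m/s decade typical of such
models. Absolute fluxes therefore carry the calibration; the invariants the
tests enforce are structural: Jv is affine in P_i with slope −Lp·S, vanishes
at the Starling equilibrium, equals its per-edge sum exactly, and is zero
whenever the patent surface is zero.

## The synthetic study and what it does (not) show

`run_study()` builds each ACU once at baseline (skeleton → calibrated mesh →
attached inlet/outlet stubs of 50-μm distribution vessels) and then only
rescales diameters per timepoint on the frozen topology: corner diameters
follow a configurable multiplier (default 1 / 0.75 / 1.15 — the observed mild
corner constriction at 30 min and moderate dilation at 120 min), distribution
stubs follow the constrict-reopen course (1 / 0.5 / 1), and septal diameters
stay at baseline since they are never measured. The default two-ACU study
contrasts a large-alveolus network (mean corner length 273 ± 76 μm) with a
smaller one (195 ± 58 μm) across baseline / 30 min / 120 min.

```{r study, eval = FALSE}
study <- run_study(
  acus = list(
    list(name = "ACU1", mean_corner_length = 273, corner_length_sd = 76,
         n_junctions = 6),
    list(name = "ACU2", mean_corner_length = 195, corner_length_sd = 58,
         n_junctions = 6)
  ),
  config = acu_study_config(seed = 1)
)
tidy(study)
autoplot(study$solutions[["ACU1 120"]])
```

What the generator emulates: dark anti-aliased vessel bands of known pre-blur
width under Gaussian optics and texture noise; eroded-Voronoi alveolar fields
with an analytic interstitial area; jittered convex corner polygons rescaled
affinely so the mean corner length is hit exactly; and the programmed
constrict-reopen / closing / stable diameter patterns. What it does not
emulate: breathing motion, illumination gradients, focal-depth artifacts,
non-convex alveoli, and real corner-diameter measurements — so passing tests
demonstrate correctness of the measurement and modeling chain on its own
stated physics, not field performance on rabbit imagery.

Problem sizes were chosen to keep a full run light: hexagonal skeletons
(6 corner junctions), calibrated meshes of roughly 300–650 interior points
(~1000–2500 edges), two inlets and two outlets, three timepoints, and
10-seed ensembles for stochastic comparisons. Larger polygons and point
counts change runtimes, not conclusions.

## Numerical choices and degenerate inputs

* Coordinates are μm with origin at the image top-left (y down); all stored
  lengths are μm, all reported flows SI. 1 cmH₂O = 98.0665 Pa.
* Duplicate Voronoi generators are re-perturbed (bounded retries, then an
  error); `N = 1` yields a mesh with no septal edges; `N = 2` a single ridge.
* An over-dense mesh whose capillary volume exceeds the barrier slab raises an
  explicit error rather than returning a negative interstitial volume.
* Zero-diameter (closed) vessels keep their place in the graph with zero
  conductance, so topology is identical across timepoints by construction.
* Inlets may not coincide with outlets; attachment positions snap to the
  nearest corner-cycle node and refuse to share one.
* The baseline full-perfusion condition (every septal edge carries flow) is
  checked after attachment; failures warn with the unperfused edge ids rather
  than erroring, since sparse access placement is a legitimate modeling state.

## Known limitations

* The binary patency rule (discussed above) postpones de-recruitment relative
  to a compliant-vessel law; absolute flow partitions depend on the sampled
  corner diameters, which in vivo are measured, not sampled.
* The 2D-to-volume bridge with a uniform barrier thickness is the simplest
  testable mapping; alveolar curvature and wall-thickness heterogeneity are
  ignored.
* Blood is Newtonian here; Fåhræus–Lindqvist effects at 5–8 μm calibers would
  lower septal conductance several-fold and shift the septal-to-corner ratio.
* Interstitial pressure is an input per timepoint, not a state variable — the
  model reports filtration under a prescribed edema trajectory rather than
  simulating fluid accumulation.
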