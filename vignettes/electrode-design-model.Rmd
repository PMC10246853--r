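---
title: "Model-based design of peripheral nerve stimulation electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based design of peripheral nerve stimulation electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nervestim` is a desk-scale simulator for comparing and optimizing
peripheral nerve stimulation electrodes *in silico*. It follows the
two-step strategy used in model-based electrode design: a cheap,
distance-only *geometric selectivity* screen drives grid-search
optimization of electrode dimensions, and a full *hybrid* model
(anisotropic volume conduction coupled to myelinated-axon membrane
dynamics) evaluates the shortlisted designs down to single-axon
resolution. This vignette documents the model, its assumptions, the
parameters that matter, and the choices made where the design was
genuinely open.

## Synthetic nerve anatomy

Nerves are generated, not segmented. A cross-section consists of an
epineurium contour and `n` fascicle contours, each obtained as the
convex hull of a 2D Gaussian point cloud smoothed by periodic cubic
spline interpolation and rescaled to a target area. Fascicle areas are
drawn (by default) from a gamma distribution normalized so that
fascicles occupy a configurable *packing fraction* of the nerve
cross-section (default 0.55, exposed as a parameter because histology
reports total and endoneurial areas inconsistently across nerves).
Each fascicle carries a perineurial sheath of thickness 3% of its
equivalent diameter; the endoneurium contour is the outer contour offset
inward by that thickness (implemented as a uniform scaling about the
centroid, exact for circles and within a few percent for the mildly
eccentric generated shapes).

Packing uses seeded rejection sampling of candidate centers for
shrunken copies of the fascicle shapes, followed by a deterministic
grow-and-relax loop (C++) that inflates the shapes to full size while
pushing violating pairs apart, pulling strays back inside the
epineurium, and allowing a jammed shape to rotate. The default minimum
clearance between fascicles is twice the largest perineurium thickness,
which prevents merged sheaths at rasterization. At the default packing
fraction the problem sits beyond the jamming limit of pure rejection
sampling, which is why the relaxation stage exists; a fascicle-area
draw that cannot be packed is resampled under a salted sub-seed, and
packing failure is a hard error with a diagnostic.

Two presets bracket the anatomy of interest:

* **pudendal-like** — flattened 2:1 elliptical epineurium, 11
  fascicles, 3.6 mm² cross-section, straight 20 mm course. The area is
  chosen so that a 2.475 mm transversal shaft spans a whole diameter
  and a 0.6 mm needle insertion stays interior, matching how those
  electrode dimensions were chosen in the first place.
* **sacral-like** — round epineurium, 10 fascicles, 5 mm²
  (≈ 5.7 × 10³ axons at the default density), swept along a circular
  arc because the nerve curves strongly at the level of interest.

The generated nerves do not branch: the cross-section topology is
constant along the sweep. Real pudendal fascicles branch and merge;
the guidance-field machinery below is written to be topology-agnostic,
but the synthetic generator deliberately trades that realism for
reproducibility. Consequences for interpretation: passing tests show
that the metrics, fields and thresholds behave correctly on realistic
*non-branching* anatomy; they do not validate behavior at branch
points, and the spikes-per-head analysis is degenerate in one specific
way (see *Limitations*).

## Fiber populations

Myelinated fiber diameters follow a two-component normal mixture with
means 3.1 and 9.2 µm. Only the means are reported in the anatomical
literature used here; the standard deviations (1.0, 2.0 µm), weights
(0.55, 0.45) and truncation interval ([1, 16] µm) are package defaults
chosen to produce the familiar bimodal shape, and all are
configurable. Axons are seeded uniformly in the endoneurium of the
central cross-section at 2.33 × 10³ axons/mm² (interpreted as the
placed, already subsampled density), with per-fascicle counts fixed by
rounding rather than Poisson draws so that a seed reproduces the
population exactly.

Axon trajectories follow the sweep of the seed point along the nerve
course. For the non-branching swept nerves generated here this is
exactly the streamline field of the guidance problem: a Laplace
(steady diffusion) equation on the fascicle interior with inlet/outlet
Dirichlet faces and zero-flux walls, whose normalized gradient defines
the local fiber tangent. `solve_guidance_field()` and
`trace_streamline()` implement the general machinery (voxelized
interior, Jacobi-preconditioned conjugate gradients, fixed-step RK4
tracing with wall projection), and the test suite cross-validates the
two routes on straight and arc-swept fascicles: interior tangents
follow the analytic arc within 3°, streamline arc lengths within 1%.
Voxels within ~3 voxels of the endoneurium wall show staircase error in
the tangent (zero-flux walls are approximated on a voxel grid); tracing
is insensitive to this because the wall projection confines the path.

Compartment chains follow the published MRG (McIntyre–Richardson–Grill)
myelinated fiber parameterization: explicit nodes of Ranvier and
MYSA/FLUT/STIN internodal sections, geometric parameters tabulated for
5.7–16 µm fibers and interpolated piecewise-linearly in diameter.
Below 5.7 µm (the generator's small-fiber component lives there) the
table is continued linearly with the slope of a least-squares fit over
the whole table, anchored at the 5.7 µm entry — naive two-point
extrapolation of the first table rows gives *negative* internode
lengths below ~2.6 µm and is unusable. The continuation keeps all
parameters positive and monotone down to 1 µm (tested). A uniform
random longitudinal shift (one internode) decorrelates node positions
across axons.

## Volume conduction

The current conservation problem ∇·(σ∇V) = 0 with a unit current source
on the active site is discretized with cell-centered finite volumes on
a rectilinear grid: uniform spacing over the nerve (default 60–80 µm,
at least 20 voxels per nerve diameter), geometrically stretched cells
through the saline padding (≥ 2 nerve diameters), and an axial spacing
refined over the electrode span. Face conductances use harmonic
averaging, which keeps the scheme conservative and handles the eight
orders of magnitude between substrate (10⁻¹⁴ S/m) and saline (2 S/m).
Conductivities: endoneurium 0.571 S/m along the fiber axis and
0.0826 S/m transverse, epineurium 0.0826 S/m, perineurium 0.00088 S/m,
saline 2 S/m, bone 0.02 S/m (a value is not reported for bone;
0.02 S/m is a standard cortical-bone figure and is configurable).

Two discretization choices deserve emphasis:

* **Perineurium as a thin sheet.** The sheath is micrometres thick and
  cannot be resolved by the voxel size; it enters as a series sheet
  resistance (thickness / σ_p, e.g. 0.0341 Ω·m² for a 1 mm fascicle)
  on every face crossing a fascicle boundary. The suite verifies the
  documented physiological consequence: with the sheet enabled, the
  potential spread inside a fascicle from an extraneural source
  shrinks ("more uniform" intrafascicular potentials).
* **Diagonal tensor projection.** The endoneurial conductivity tensor
  σ = σ_l t⊗t + σ_t(I − t⊗t) is projected onto the grid axes
  (σ_axis = t_axis² σ_l + (1 − t_axis²) σ_t). A 7-point stencil cannot
  represent the off-diagonal terms (that needs a multi-point flux
  approximation); the projection is exact wherever fibers run along a
  grid axis — all straight-nerve studies — and approximate on curved
  sweeps. The tensors themselves are full-rank and their principal
  axes align with the fiber tangents by construction (tested to < 3°).

The SPD system is solved by Jacobi-preconditioned conjugate gradients
(relative tolerance 10⁻⁸ by default; the studies use 10⁻⁶, which
changes thresholds by far less than the bisection tolerance). Sources
inject the current uniformly over the voxels of the active-site
geometry (disc footprint, band section, or exposed tip segment); there
is no electrode–electrolyte double layer. The outer box boundary is
grounded (V = 0), so potentials outside the solved box are consistently
continued as zero when sampling long axons. Against closed forms, the
solver reproduces the isotropic Coulomb kernel within 5% and the
anisotropic point-source kernel within 7% (after removing the constant
grounded-boundary image offset, which is a property of the finite
domain, not of the discretization).

## Membrane dynamics and thresholds

The stimulus is a single cathodic square pulse, 50 µs wide; threshold
charge = amplitude × width. Nodal membranes carry the MRG channel set
(fast Na⁺, persistent Na⁺, slow K⁺, leak; rates at 36 °C with the Q10
factors folded in; resting potential −80 mV). Two cable variants exist:

* **full** — the double-cable MRG model with an explicit periaxonal
  space under the myelin (MYSA/FLUT/STIN), integrated by backward
  Euler on an interleaved banded system;
* **reduced** — nodes plus one lumped passive myelinated compartment
  per internode (axolemma in series with the myelin), a single cable.
  This is the default threshold engine for studies; outputs carry the
  `detail` flag. On matched fibers the two variants agree in
  recruitment order and stay within a factor ~2 in absolute threshold
  (tested); all comparative results in the package are
  reduced-vs-reduced comparisons.

Integration is implicit (backward Euler) with Rush–Larsen gate updates
from lookup tables; the default step is 1 µs over a 2 ms window (the
large studies use 2 µs, which changes thresholds by under 2%). A spike
is an upward 0 mV crossing at *both* terminal nodes — a propagation
check that rejects local non-propagating depolarizations. Threshold
search brackets the amplitude by geometric expansion (warm-started from
the previous axon's threshold within a site, seeded from the activating
function otherwise) and then bisects geometrically until the relative
bracket width is below 1%. Fibers silent at the amplitude cap are
flagged unreachable and treated as +∞ downstream. Numerical sanity
properties under test: resting stability over 10 ms, exact linearity
(doubling the lead field halves the threshold), zero excitability under
spatially uniform potentials, strength–duration behavior (lower
threshold *current* at 500 µs than at 50 µs), and determinism.

## Metrics

All benchmark metrics derive from the axon × site threshold matrix:

* **Recruitment threshold** of a fascicle: the charge recruiting 10% of
  its axons — the ⌈0.1 n⌉-th order statistic of its thresholds, at the
  best (cheapest) site. Thresholds are stable across 5–15% recruitment
  levels because recruitment curves are steep around threshold.
* **Fascicular selectivity**: target recruitment minus the mean
  recruitment of the other fascicles. The operating point is the
  charge at which the target reaches the 10% level, evaluated per
  site and maximized over sites — the "best available site" rule
  applied consistently with the threshold definition. Note the metric
  is then bounded near the recruitment level itself (a perfectly
  selective site scores ≈ 0.1 + 1/n); comparisons across electrodes
  and the correlation against the geometric surrogate are unaffected
  because the bound is common to all configurations.
* **Axonal selectivity** 1 − n_coll/N, where n_coll is the smallest
  number of other axons co-recruited with the target over all sites
  (ties count as recruited together, per the inclusive ≤ in the
  definition; the formula's floor is 1/N, reached when the target is
  recruited last everywhere). The implementation is verified against a
  brute-force enumeration on 500 random matrices.
* **Geometric selectivity** 1 − d_min,i / mean_j(d_min,j): the
  distance-only surrogate, computed in the cross-section plane from
  site centers to fascicle outer contours (zero inside a fascicle),
  best site per target. It costs microseconds, which is what makes
  grid-search design optimization affordable.

## Studies

The study layer reruns the design experiments: grid-search optimization
of spike pitch and length, site-count saturation (the AIR adds whole
heads, keeping 2 spikes per surface site), spikes-per-head increments,
the geometric-vs-fascicular correlation (12 configurations spanning all
four electrode families over 4 synthetic nerves, 3 placements each),
adaptability (cross-sections scaled up to 9× in area with fascicle
count, fascicle areas and site counts scaled with the equivalent
diameter — kernel-density resampling of the reference fascicle areas),
repeatability across placements (one-way ANOVA per metric, Bonferroni
pairwise), diameter-class analysis (small < 6 µm vs large fibers,
4 surface sites vs one spike per head — the first spike of each head by
default — two-way ANOVA with interaction), and a Kolmogorov–Smirnov
comparison of per-placement best thresholds against an experimental
charge sample supplied as CSV (none is bundled).

Statistical machinery is base R (`aov`, `TukeyHSD`, `pairwise.t.test`,
`ks.test`); the package's contribution is the experiment orchestration,
the designs, and the metrics, not the statistics.

Problem sizes for the shipped acceptance script: 12 configurations,
4 nerves, 8 axons per fascicle (88 per configuration), 70 µm grids,
2 µs membrane step — chosen so the whole recomputation runs on one CPU
in well under half an hour. The test suite runs the same studies at
slightly smaller sizes. These sizes are the package's reproducibility
settings, not statements about convergence; doubling any of them is a
one-argument change.

## Known limitations

* Prismatic nerves make the 2D geometric surrogate independent of
  *longitudinal* electrode dimensions: the optimization surface is flat
  in spike pitch (the tie-break prefers the least invasive design), and
  a third spike per head adds ≈ 0 geometric selectivity rather than
  "a little". On real, longitudinally varying anatomy both effects are
  small but nonzero.
* The histology-derived axon count of the flattened preset does not
  match its area under the default packing fraction: real pudendal
  cross-sections are far sparser (endoneurium ≈ 15% of the
  cross-section) than the 0.55 default. The default follows the
  package's single packing-fraction convention; set
  `packing_fraction = 0.15` to emulate the sparse anatomy.
* No unmyelinated fibers, no branching fascicles, no chronic foreign
  body response, no electrode double layer, no mechanical deformation
  at insertion. Absolute thresholds are therefore best read
  comparatively (electrode A vs electrode B on the same nerve), not as
  clinical predictions.
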