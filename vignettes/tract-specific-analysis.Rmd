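---
title: "Tract-specific analysis on medial skeleton models: methods and design notes"
author: "tractfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractfa)
```

# The model and its assumptions

## Medial representation

A white-matter tract, given as a binary volume, is represented by its
**medial skeleton**: a surface running through the middle of the shape,
with two **spokes** per skeleton point — segments to the nearest
boundary point on each side. Spokes of an exact medial model are
orthogonal to the boundary, never cross one another, and their length
equals the distance-transform value at the skeleton point; together
with a depth fraction in [0, 1] they define a coordinate system
(surface position × depth) for everything inside the tract.

`build_medial_model()` realizes this discretely:

1. an exact Euclidean distance transform (separable
   lower-envelope-of-parabolas algorithm, anisotropic spacings in mm)
   with nearest-boundary *feature* propagation;
2. **maximal-ball medial detection**: a voxel is medial when, besides
   its nearest boundary contact, it has a second contact in a
   near-opposite direction (angular separation above
   `medial_angle_deg`, default 160°) at most `~1.6` voxels farther
   away. Anchoring the test at every *exactly tied* nearest contact
   makes it independent of distance-transform tie-breaking — the
   earlier neighbour-feature ridge test we tried was not, and produced
   asymmetric artifacts on even-thickness slabs;
3. largest 26-connected component, then spur pruning (`prune_iter`
   passes removing voxels with ≤ 1 neighbours, i.e. branches shorter
   than 3 voxels by default — branch anatomy is out of scope);
4. meshing: medial voxels are projected onto their principal (PCA)
   tangent plane, binned at the voxel pitch (bins anchored on a lattice
   point; plain rounding at half-integer bin edges is numerically
   unstable), one vertex per occupied cell at the mean world position,
   and triangulated as a height field. A footprint thinner than 3 cells
   — a tube-like shape whose medial set degenerates toward a curve — is
   dilated once inside the mask so the model still returns a thin
   surface *ribbon* with nonzero area;
5. spokes: per vertex, the nearest boundary voxel center inside a
   `spoke_cone_deg` (70°) cone around the ±vertex normal, falling back
   to the half-space and then to the global nearest. The cone matters
   at sheet rims, where an oblique rim point can be closer than the
   facing boundary; among near-ties the more normal-aligned candidate
   wins;
6. per-vertex area elements: one third of the incident triangle areas,
   so vertex areas sum exactly to the mesh area (cluster areas in mm²
   inherit this conservation).

**Rim caveat.** At interior mesh vertices the spoke–boundary-normal
angle is numerically zero on slab and tube phantoms. Vertices on the
open mesh boundary — in particular the edge of the ribbon that stands
in for a degenerate tubular medial axis — can deviate substantially;
`mesh_boundary_vertices()` identifies them, and the orthogonality
property is only promised for interior vertices. Tube orthogonality is
evaluated at a radius of ≥ 4 voxels; a 2-voxel-radius cylinder has too
coarse a discrete boundary for local normals to mean much.

## Projection

`project_max_fa()` samples the FA volume by trilinear interpolation at
evenly spaced depth fractions along both spokes and keeps the maximum —
one value per skeleton vertex. The along-spoke step defaults to 0.25 of
a voxel; the sample count per spoke is rounded up to a power of two so
that halving the step yields a superset of sample points, making the
projected value monotone under refinement (a tested invariant, along
with dominance over the skeleton-point value and range preservation).
Max projection assumes the tract is a *ridge* of FA — the highest FA
along a depth line belongs to the tract core, so projection collapses
the depth direction without mixing in neighbouring structures.

## Inference

Pointwise statistics on the skeleton are the pooled-variance two-sample
t (`pointwise_ttest()`, df = nA + nB − 2) or the simple-regression
slope t (`pointwise_regression()`, df = n − 2). The map is thresholded
at the t-quantile for an uncorrected height p (`height_threshold()`;
one-sided uses 1 − p, two-sided 1 − p/2), supra-threshold vertices are
grouped into connected components of the mesh edge graph
(`form_clusters()`), and cluster areas are referred to the permutation
null distribution of the **maximum** cluster area under group-label
shuffles (contrasts) or score shuffles (regressions), computed by a
compiled union-find over the mesh (`permutation_fwe()`):

* `fwe_p = (1 + b) / (1 + m)`, where `b` counts null maxima ≥ the
  observed area (ties count against the cluster, with a hair of
  floating-point tolerance so the observed labeling registers as a tie
  in exhaustive mode) and `m` is the number of relabelings;
* when the number of distinct relabelings is ≤ `n_perm` the null is
  enumerated exactly (all C(n, nA) subsets, or all n! score orders for
  n ≤ 9) with a message — for 3-vs-3 designs p-values are multiples of
  1/21;
* two-sided maps cluster on |t|, so a cluster may mix signs; the
  one-sided defaults (patients < controls, score–FA slope > 0) avoid
  this in practice.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `voxel_size_mm` | 2.2 | mm | isotropic clinical diffusion voxel |
| `n_per_group` | 13 / 11 / 34 | subjects | published study design |
| `baseline_fa` | 0.45 | FA | typical deep white matter |
| `background_fa` | 0.25 | FA | tissue outside the tract; must stay below baseline so the tract is an FA ridge (see below) |
| `fa_noise_sd` | 0.03 | FA | marginal SD of the smoothed field (calibrated after smoothing, not before) |
| `smoothness_mm` | 6 | mm FWHM | smooth fields make cluster inference meaningful |
| `truncate_z` | 6 | group SDs | guards against absurd score draws; relative to each group's own mean because one published group mean sits at −13.2 z |
| `n_perm` | 10,000 | — | published permutation count |
| `height_p` | 0.005 / 0.01 | — | published contrast / regression height thresholds |
| `cluster_alpha` | 0.05 | — | FWE cluster threshold |
| `medial_angle_deg` | 160 | degrees | opposition angle for maximal-ball detection; 180° ideal sheet, oblique rim wings fall well below |
| `spoke_cone_deg` | 70 | degrees | spoke search cone around the vertex normal |
| `step_fraction` | 0.25 | voxels | along-spoke sampling step |

# What the generator emulates — and what it does not

`simulate_cohort()` produces, reproducibly from one seed: group labels
at the published sizes; Animals and BNT z-scores from per-group normal
distributions (patients from the published means/SDs, controls standard
normal by construction of a z-reference); and per-subject FA volumes
over a tract phantom — baseline inside the mask, a lower background
outside, plus Gaussian noise smoothed to `smoothness_mm` and rescaled
so its *marginal* SD equals `fa_noise_sd`, all clipped to [0, 1].
Lesions subtract `delta_fa` inside a sphere ∩ mask for targeted groups;
couplings add `beta ×` score inside a region. Under no lesions and no
couplings, group labels are exchangeable by construction, which is what
the type-I-error calibration of the permutation engine tests.

The background level is a deliberate part of the stated world: with a
flat FA landscape the max-projection would pick up unlesioned baseline
from just outside the mask at the spoke ends and no lesion could ever
be seen. Real tracts are FA ridges; the phantom must be one too.

Not emulated: raw diffusion-weighted signals, realistic eigenvector
fields, registration error, head motion, spatially varying noise,
between-tract anatomy, or any correlation between scores and FA beyond
the explicit couplings. A green test therefore establishes that the
*pipeline* is correct and calibrated on fields with the stated
covariance structure — not that effect sizes on real data will match.

# Numerical choices

* Distances are measured between voxel centers; the distance transform
  is exact for that convention, and spoke lengths agree with it to
  within one voxel diagonal (tested against a brute-force oracle).
* Trilinear samples outside the voxel-center hull are errors in
  `sample_along_spoke()` and are dropped in `project_max_fa()` (a
  vertex whose spokes sample entirely outside the volume is an error).
* FA is computed from closed-form symmetric-3×3 eigenvalues (Cardano
  trigonometric form, verified against `eigen()`), clamped to [0, 1];
  all-zero tensors give FA 0 with a warning, negative eigenvalues are
  counted and reported.
* Zero-variance vertices get t = 0 (counted); exact-fit regression
  vertices are capped at t = 10⁶ (counted) rather than ±Inf.
* Degenerate (zero-area) triangles are excluded from vertex areas with
  a warning.
* Permutation matrices are processed in blocks of 2,000 to bound
  memory; the RNG state is saved and restored around every seeded
  operation, so library calls never perturb a caller's stream.

# Open design choices

* **Two spokes per vertex.** A strict closest-point reading gives one
  spoke per skeleton point; we emit both sides, since the depth
  coordinate needs them and the slab's two sides are symmetric. At
  ribbon rims the two sides can collapse toward the same boundary
  region; documented above.
* **Per-tract familywise correction.** Cluster-size correction is
  applied within a tract (one null distribution per tract), matching
  per-tract reporting; correcting across all tracts simultaneously
  would be stricter and is left to the caller (run the engine on a
  concatenated model if desired).
* **Regression gating.** `tsa regress` refuses tracts without a
  significant prior FA disruption unless `--no-restrict-to-diseased`
  is passed, so score regressions are only read where disease exists.
* **JSON configuration** rather than YAML (no YAML parser among the
  package's dependencies), RFC-4180 CSV, NIfTI-1 `.nii.gz`, and VTK
  legacy ASCII polydata with a JSON provenance sidecar.

# Known limitations

* The skeleton is a discrete stand-in for a continuous deformable
  medial model: vertices sit at voxel-mean positions, not at an
  optimized medial manifold, and strongly curved or branching medial
  sets are reduced to their largest sheet.
* Meshing assumes the medial sheet is a height field over one plane;
  shapes whose skeleton folds over itself (e.g. a torus-like tract)
  are out of scope.
* Permutation inference assumes exchangeability under the null; no
  nuisance covariates are modeled in the default design.
* The NIfTI reader supports the package's own output dialect
  (3-D, world-aligned sform, little-endian) plus common scalar types;
  it is not a general NIfTI implementation.
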