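---
title: "Structure-guided deformable registration and its QA metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided deformable registration and its QA metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdir)
```

## The problem

Registering a radiotherapy planning CT to a post-treatment, contrast-enhanced
MRI of the liver is hard for three compounding reasons: the two scans are
acquired months apart under different immobilization (abdominal compression at
planning only), the irradiated liver loses on the order of 20% of its volume
between the scans, and CT and MRI grayscales are unrelated, so
correlation-style similarity is useless. `sgdir` implements the registration
engines used to attack this problem — rigid alignment, intensity-driven
B-spline deformable registration (DIR), and a structure-guided hybrid
(SG-DIR) — together with the registration QA metrics recommended by AAPM
TG-132, and a synthetic phantom generator that reproduces the scenario's
difficulties so that the whole chain can be validated end to end without
patient data.

## Transforms

Rigid transforms carry six degrees of freedom: a translation plus ZYX Euler
angles about a stated center (we use the ROI centroid; the parameterization is
a documented convention, any consistent 6-DOF choice is equivalent).
Deformable transforms are cubic B-spline free-form deformations: a lattice of
3-vector coefficients on an axis-aligned grid with spacing `control_spacing_mm`
(default 30 mm). Displacement at a point is the tensor-product cubic B-spline
sum over its 4×4×4 coefficient support, so the field is C², has compact
support, and is exactly zero when all coefficients are zero. All physical
coordinates are millimetres; voxel indices are 0-based; the world frame is the
NIfTI sform frame (nominally LPS). Displacement fields use the fixed-grid
pull-back convention — the vector stored at a fixed-image voxel points to the
corresponding physical location in the moving image — which is also the
convention assumed for imported fields (a YAML sidecar records it; exporting
software does not always state whether its fields are forward or inverse, so
the convention here is a documented package choice).

## The registration cost

All engines maximize normalized mutual information,
NMI = (H(F) + H(M)) / H(F, M), over a region of interest chosen to encompass
the whole liver (mask bounding box padded by 20 mm by default). Two NMI
estimators are deliberately kept distinct:

* the *reporting* form (`nmi()`), a hard-binned joint histogram — this is the
  quantity with the textbook properties (range (1, 2], exactly 2 for an image
  against itself);
* the *optimizer* form, which bins the moving image but spreads each sample
  over its 8 neighbouring voxels with trilinear (partial-volume) weights.
  This makes the cost continuous in the transform parameters and gives an
  analytic gradient with respect to every B-spline coefficient at a cost
  linear in the number of samples.

Two numerical details matter in practice and are worth recording. First,
histogram metrics have a well-known grid-alignment artifact: when the two
voxel lattices coincide exactly, the joint histogram is spuriously sharp and
the metric has a false optimum at that alignment. We therefore sample the
fixed ROI at positions jittered off-grid by up to ±0.45 voxel (seeded, hence
deterministic). Second, rigid optimization is started from a center-of-mass
alignment of the binarized body masses, which places the start inside the NMI
capture basin; without it the multi-resolution search can park at an
uninformative local optimum.

The structure-guided cost is

C = w_I · C_NMI + w_S · C_struct,  with w_S = 0.10 and w_I = 0.90 by default,

where C_NMI = −NMI and C_struct is a weighted mean of squared distances (mm²)
over correspondence pairs. The 10/90 split is the method's defining constant.
Because an information-theoretic term and a mm² term have no common scale,
each term is normalized by its magnitude at the initial (rigid-baseline)
transform, so the weights act on relative improvements. This normalization is
the largest inference the package makes beyond the method's published
description, and it is applied *once*: renormalizing the structure term as it
converges would amplify its gradient without bound and measurably degrades
interior accuracy (we observed exactly this before fixing the behaviour).

Correspondences come in two groups: surface pairs (moving-surface samples
matched to the nearest fixed-surface point, re-estimated each outer iteration
as the transform improves — an ICP-style loop) and landmark pairs (exact,
name-matched centers). Surface residuals are penalized only along the
moving-surface normal (point-to-plane): nearest-neighbour pairing is
tangentially arbitrary, and penalizing the full 3-D residual drags tissue
sideways along the boundary — we measured this as a systematic worsening of
interior landmark error whenever surface guidance was enabled, which the
normal projection removes. Normals are estimated from the gradient of the
smoothed mask indicator. Each group is normalized by its own magnitude at
the initial transform and the groups are then summed, so adding landmark
guidance never weakens the surface pull; landmark-only or surface-only
guidance simply has one group.

The deformation is optimized with L-BFGS (analytic gradient; a backtracking
gradient-descent option exists) over an image pyramid — images smoothed and
downsampled by 4/2/1 with three levels by default. The B-spline lattice keeps
one fixed control spacing across levels rather than refining per level: the
result is then exactly one B-spline transform, composition bookkeeping
disappears, and the image pyramid already supplies the coarse-to-fine
behaviour. Plain DIR is the same machinery with no correspondence term (and
runs the identical outer-loop structure, so setting `structure_weight = 0`
with guidance supplied reproduces plain DIR bit for bit). A bending energy
(squared second differences of the lattice) is applied at the very small
default weight 2×10⁻⁴. We initially ran without it, intending to leave
folding fully observable, but an unregularized lattice fails the method's
own sanity property: registering an image to itself drifted by many
millimetres, because coefficients in regions the histogram metric cannot
constrain — the featureless organ interior, out-of-ROI corners — wander
freely, and sub-voxel "histogram sharpening" deformations even gain a
little cost. The default weight is calibrated to pin those unconstrained
directions (self-registration stays below 0.1 mm) while remaining orders
of magnitude too weak to suppress a genuine fold, so the Jacobian folding
analysis keeps its meaning; set the weight to 0 for a fully unregularized
fit.

## QA metrics

* **DSC** 2|A∩B| / (|A|+|B|), voxel-count based, after nearest-neighbour
  resampling onto the reference grid if needed.
* **MDA** (mean distance to agreement): surfaces are the centers of masked
  voxels with a six-connected background neighbour; each surface point of B
  contributes its minimum distance to A's surface; the directed form is the
  default (a symmetric variant is a flag away, since reference
  implementations differ). Distances are point-to-point; the discretization
  error this accepts is roughly half a voxel and is visible in the
  sphere-pair tests.
* **TRE**: per-landmark Euclidean distance after mapping the fixed-image
  landmarks through the registration, with median/range/mean/SEM summaries.
* **Jacobian map**: J = det(I + ∂u/∂x) by central differences in physical mm
  (one-sided, and flagged invalid, at array boundaries). The identity term is
  included so that J = 1 means no volume change, J < 1 contraction, J < 0
  folding; a displacement-derivative-only determinant would assign 0 to the
  identity and is therefore not what the interpretation demands. Anisotropic
  spacing is handled by differentiating in mm, not in voxels.
* **Cumulative displacement histogram**: for thresholds k·bin_width (0.1 mm
  default), the fraction of valid masked voxels with ‖u‖ below threshold;
  monotone, ending at 1; reported with mean and SEM of ‖u‖. Fields are
  resampled to the planning grid first (`resample_to_grid`), with
  out-of-support voxels zero-filled and excluded via the validity mask.

## The phantom generator

The generator emulates the study conditions rather than any particular
patient: a planning-CT-like fixed image on a 1.37×1.37×3 mm grid and an
MRI-like moving image on a 0.8×0.8×2.5 mm grid (64×64×36 and 110×110×44
voxels by default, a ~88×88×108 mm field of view — large enough to hold the
organ and its surroundings while keeping a full pair generable in seconds).
Anatomy is defined analytically in a canonical frame: a lobed ellipsoidal
liver (semi-axes 30/24/38 mm), two recursively bifurcating vessel trees whose
branch points are the landmark candidates (6–11 drawn per case), a soft-tissue
body, and three liver-isointense structures resting against the organ surface.
The last of these encode the clinical reason contour guidance exists: organs
like the diaphragm or heart can be isointense with liver in both modalities,
making stretches of the boundary invisible to any intensity metric while the
expert contour still knows where they are.

The ground-truth fixed→moving map composes (i) the inverse of an analytic
anterior–posterior compression applied to the fixed rendering only (peak
8 mm — the immobilization-device effect), (ii) a random smooth B-spline warp
(40 mm knots, 5 mm coefficient SD — chosen so pre-registration landmark error
sits in the 5–8 mm range reported for this scenario), (iii) a global
isotropic shrink realizing the 20% organ volume loss, and (iv) a random
global shift (±5 mm per axis — inter-scan setup difference). Warps whose
Jacobian drops below 0.25 in the organ are redrawn (at most 5 attempts). The
moving image is rendered by numerically inverting the map (fixed-point
iteration; the fold-rejection bound guarantees contraction), while moving
landmarks are defined as the exact ground-truth image of the fixed landmarks —
so the evaluation chain has an exact zero: ground-truth-mapped landmarks have
TRE identically 0.

Two calibrations are built in rather than asserted. The global shrink factor
is solved from the measured fixed-mask volume and the warped canonical volume
so that the rendered mask pair realizes the requested volume-change fraction
(a fixed analytic factor would be biased by the compression term). And the
intensity class levels — CT (air −1000, soft 30, liver 60, vessel 84), MR
(air 10, soft 130, liver 60, vessel 150) — were chosen to make the class
mapping non-monotone with body-wise Pearson correlation below 0.3, so that
only mutual information links the modalities, while keeping the vessel
contrast moderate on CT (contrast-phase matching makes vessels visible on a
planning CT, but far less conspicuous than on hepatobiliary-phase MRI).

What the phantom does *not* model: anatomically correct hepatic segments,
respiratory motion and 4D phases, MRI bias fields and distortion,
observer contouring variability (landmark jitter is available separately via
`corrupt_landmarks`), and dose effects on intensity. Passing tests on this
phantom therefore demonstrate that the algorithms and metrics behave as
specified under controlled deformations — not that clinical accuracy on real
scan pairs would match.

## What the desk-scale experiments show

`run_cohort_experiment()` regenerates the study's comparison shape at reduced
size: seeded cohorts of phantom cases, four arms per case (rigid; DIR;
SG-DIR with liver surfaces; SG-DIR with surfaces plus landmarks), TG-132
metrics per arm, Wilcoxon signed-rank comparisons, and the check that cohort
median TRE and MDA decrease monotonically from rigid through DIR and
SG-DIR(liver) to SG-DIR(liver+landmarks). The cohort-scale tests run the
phantom at 32×32×20 (fixed) / 44×44×24 (moving) voxels with proportionally
coarser spacing, 10 cases per cohort and 5 cohort replicates — sizes chosen
so a full replicate completes in a few minutes on one core while the
between-arm differences remain larger than the discretization floor. The
experiment's engine settings are a 30 mm lattice, a two-level pyramid, two
correspondence rounds per level, 250 surface samples, and the default
bending weight.
Because the landmark-guided arm is evaluated on the same landmarks that
guided it (as in the source workflow), its TRE is optimistic; the package
also reports TRE on a held-out landmark subset (50% by default) when asked
(`held_out_tre = TRUE`), and the held-out numbers are the fairer statement
of accuracy.

## Statistics

The Wilcoxon signed-rank test discards zero differences, average-ranks ties,
uses W = min(W+, W−), and computes the exact two-sided p-value by
enumerating all 2^n sign assignments (via the shifted-convolution
distribution of W+, tie-aware) for n ≤ 25; beyond that a normal
approximation with continuity and tie corrections is used. Degenerate input
(all differences zero) is an error, not a p-value. Raw pairwise p-values are
reported at α = 0.05 with no multiplicity correction by default (a Holm
option exists), matching common practice of reporting unadjusted pairwise
tests; summaries are median (range) and mean ± SEM with SEM = σ/√n and the
n−1 standard deviation.

## Numerical choices and degenerate inputs

* Joint histograms use 64 bins; probabilities are ε-regularized (10⁻¹⁰)
  before logs so gradients stay finite.
* NMI of a constant image is an error (zero marginal entropy), as is a DSC
  of two empty masks, an MDA of an empty mask, and a histogram over an empty
  ROI — degenerate inputs fail loudly rather than returning conventional
  values.
* Out-of-support resampling fills with the moving image minimum (air stays
  air-like) for volumes, zero plus a validity flag for displacement fields.
* Optimizer tolerances: relative cost change 10⁻⁵ (mapped to L-BFGS's
  `factr`), at most 100 inner iterations per level split across the outer
  correspondence re-estimation rounds.
* Every stochastic step (phantom draw, ROI jitter, surface sampling) is
  seeded explicitly; identical inputs, configuration and seed reproduce
  results bit for bit.

## Known limitations

Parity with the commercial implementation the method description comes from
is claimed only at the level of cost structure and weights — its
correspondence construction, optimizer, pyramid schedule and term
normalization are proprietary, so absolute metric values are not
comparable; directions of effect are. MDA is point-cloud-based rather than
mesh-based, which overestimates distances by up to about half a voxel on
coarse grids. The phantom's confounder structures are a stylized stand-in
for isointense neighbouring anatomy. Registration of images with strongly
oblique orientation matrices is supported by the data model but the FFD
lattice is world-axis aligned, which is the usual convention but makes the
effective knot spacing anisotropic relative to an oblique volume.
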