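# sgdir — structure-guided deformable registration and TG-132 QA for multimodal liver imaging

`sgdir` is an R toolkit for the registration problem that arises when a
radiotherapy planning CT of the liver must be aligned with a
contrast-enhanced MRI acquired months after stereotactic body radiation
therapy: the organ has lost roughly 20% of its volume, the planning scan was
acquired under abdominal compression, and CT/MRI grayscales are unrelated.
It provides:

* **Registration engines** — rigid (6-DOF, normalized mutual information),
  intensity-driven B-spline deformable registration (DIR), and
  structure-guided DIR (SG-DIR), whose cost blends NMI with a
  structure/landmark correspondence term at the method's defining
  weighting:

  C = 0.9 · (−NMI) + 0.1 · C_struct,
  NMI = (H(F) + H(M)) / H(F, M),
  C_struct = Σᵢ wᵢ ‖T(pᵢ) − qᵢ‖² (mm²),

  each term normalized by its value at the rigid baseline. Guidance comes
  from expert structure contours (ICP-style surface correspondences,
  re-estimated as the transform improves) and/or paired anatomical
  landmarks treated as overlaid centers.

* **TG-132 QA metrics** — Dice similarity coefficient
  (DSC = 2|A∩B|/(|A|+|B|)), mean distance to agreement (MDA, directed mean
  surface distance), target registration error
  (TRE = √(Δx²+Δy²+Δz²) per landmark), the Jacobian-determinant map
  J = det(I + ∂u/∂x) with its negative-fraction folding analysis, and masked
  cumulative displacement histograms.

* **A seeded synthetic phantom** — paired CT-like / MRI-like liver volumes
  with vessel-bifurcation landmarks, a known ground-truth deformation
  (20% shrinkage, smooth random warp, planning-side compression), and
  deliberately non-monotone intensity maps, so every stage of the pipeline
  can be validated against ground truth without patient data.

* **Cohort statistics** — exact (sign-enumeration) Wilcoxon signed-rank
  tests, median/range and mean ± SEM summaries, and per-arm comparison
  tables.

File formats: NIfTI (`.nii`/`.nii.gz`) for volumes, masks and displacement
fields (with a YAML sidecar recording the fixed-grid pull-back convention),
CSV/JSON for landmarks.

## Worked example

```r
library(sgdir)

# one synthetic case: CT-like fixed scan, MRI-like moving scan, liver
# masks, 6-11 vessel-bifurcation landmarks, known ground truth
case <- make_case(phantom_spec(rng_seed = 11))

cfg <- registration_config(roi = roi_from_mask(case$fixed$mask, 20),
                           pyramid_levels = 2, max_iters = 60,
                           outer_iterations = 3)

rigid <- register_rigid(case$fixed$volume, case$moving$volume, cfg)
sg <- register_deformable(case$fixed$volume, case$moving$volume, rigid, cfg,
                          guidance = structure_guidance(
                            case$fixed$mask, case$moving$mask,
                            case$fixed$landmarks, case$moving$landmarks))

qa_report(sg$transform, case$fixed$mask, case$moving$mask,
          case$fixed$landmarks, case$moving$landmarks)
#> <qa_report> DSC 0.937; MDA 1.2 mm; TRE median 1.1 mm; %J<0 0
```

Read: after structure-guided registration the warped liver overlaps the
planning contour at DSC 0.937 with a 1.2 mm mean surface distance, the
guidance landmarks land within about a millimetre of their targets, and no
voxel of the liver folds (J < 0 nowhere). The same case evaluated with
`rigid` alone gives DSC 0.878 and TRE median 2.35 mm — the gap the
deformable arms close.

`run_case_arms()` runs all four arms (rigid, DIR, SG-DIR with liver
surface, SG-DIR with surface + landmarks) on a case;
`run_cohort_experiment()` does so over a seeded cohort and adds per-arm
summary tables, pairwise Wilcoxon signed-rank tests, and a check of the
expected ordering (median TRE and MDA decreasing from rigid to
SG-DIR liver+landmarks).

A thin command-line wrapper is installed with the package
(`system.file("cli", "sgdir", package = "sgdir")`) with subcommands
`phantom`, `register`, `evaluate` and `report`; see `?sgdir_cli`.

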