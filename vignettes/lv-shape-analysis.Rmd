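---
title: "Statistical shape analysis of LV outflow-tract remodelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of LV outflow-tract remodelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvshape)
```

## Overview

`lvshape` quantifies left-ventricular (LV) remodelling associated with
outflow-tract obstruction in hypertrophic cardiomyopathy as a single
discriminant axis in the coefficient space of a statistical shape model. The
pipeline is: corresponded surface meshes (generated synthetically, or
personalized from short-axis segmentations) → generalized Procrustes
alignment → PCA point-distribution model → Fisher linear discriminant between
clinical groups → per-subject Z-scores, ±3 SD extreme anatomies, AHA
17-segment thickness maps, and AUC validation.

The pipeline's statistical core assumes only that shapes are *corresponded*
(node k means the same anatomical location in every subject) and
approximately Gaussian in coefficient space. Everything upstream exists to
manufacture and check that correspondence.

## Anatomical frame and conventions

One documented convention serves every module:

* the LV long axis is *z*, the base plane is *z* = 0, the apex points toward
  negative *z*;
* *u* ∈ [0, 1] is the longitudinal fraction from base to apex;
* θ is the circumferential angle, counter-clockwise viewed from the apex,
  with θ = 0 at the centre of the anteroseptal outflow (LVOT) sector; the
  septum occupies a fixed 120° sector around θ = 0;
* the LVOT sector used for effective outflow area is the basal third
  (*u* < 1/3), θ ∈ [−30°, +30°];
* AHA segments: basal and mid levels are 6 × 60° sectors (anteroseptal
  centred on θ = 0, so segment 2 covers the LVOT sector), the apical level is
  4 × 90°, and the apex-pole grid row is segment 17; the bull's eye is viewed
  from the apex.

Threshold comparisons on pressure drops are inclusive (≥ 30 mmHg at rest is
obstructive, ≥ 50 mmHg severe); the boundary case "exactly 30 mmHg" is
classed obstructive by that rule. Missing stress measurements exclude a
subject from the stress comparison — never imputed.

## The synthetic world

The generator states one fixed, physiologically plausible world; its
defaults are not tuned to any test outcome.

The endocardium is a surface of revolution
`r_endo(u) = Re * sqrt(1 - u^s) * (1 + d_ap * u^2)` (a semi-ellipsoid for
sphericity exponent *s* = 2, with apical dilatation `d_ap`), the epicardium
is offset outward along the meridian normal by a thickness field
`t(theta, u) = t0 + A_sept * G(theta, u)` with a Gaussian septal bump *G*
(centre drifting by `spiral_drift_rad * u` for spiral hypertrophy patterns),
and both surfaces are displaced radially inward by an LVOT remodelling bump
centred on (θ = 0, u = 0). Because every mesh shares one (θ, u) grid,
correspondence holds by construction.

Default group distributions (means; truncated-normal draws at ±3 SD):

| parameter | nonobstructive | obstructive | SD | why |
|---|---|---|---|---|
| length L (mm) | 80 | 86 | 6 | normal-to-long LV; lengthening is part of the signature |
| base radius Re (mm) | 25 | 25 | 2 | typical end-diastolic cavity |
| wall thickness t0 (mm) | 8 | 9 | 1 | hypertrophic baseline |
| septal bump A_sept (mm) | 4 | 9 | 1.5 | 17 mm peak wall (t0 + A_sept) in the obstructive group |
| apical dilatation d_ap | 0.05 | 0.12 | 0.03 | mild vs marked apical dilatation |
| LVOT inward A_lvot (mm) | 1 | 6 | 0.8 | outflow narrowing drives the gradient |

Pressure drops follow the clinical chain: the effective LVOT sector area
`A_sector` is measured on the generated mesh, the reference area `A_ref` is
the same subject with the inward remodelling removed, the peak velocity is
`v = v0 * (A_ref / A_sector) * noise` with `v0 = 2.3` m/s and 15% lognormal
coefficient of variation, and `drop_rest = 4 v^2` (simplified Bernoulli,
mmHg). A subject needs v ≥ 2.74 m/s to reach the 30 mmHg threshold, so
obstruction is shape-driven but noisy — group labels overlap, as they do
clinically. Stress drops use a per-subject multiplier κ ~ 1 + |N(0.4, 0.2)|,
creating subjects obstructive only at stress; 70% of subjects have a stress
test. Genotype-positive fractions are 0.45 (nonobstructive-leaning group)
vs 0.30 (obstructive), encoding the association of genotype-*negative*
disease with the more obstructive anatomy.

What the generator does **not** emulate: trabeculation, papillary muscles
and the mitral apparatus, motion/torsion, segmentation artefacts, and —
importantly — the high-dimensional variance spectrum of a real cohort. The
generator has ~8 latent factors, so its PCA spectrum is low-rank: typically
2–3 modes reach 90% cumulative variance, against ~25 modes in a real
population. A green pipeline test therefore establishes correctness of the
machinery and recoverability of planted signals, not clinical effect sizes.

## Voxelization and contours

`voxelize()` mimics short-axis cine acquisition: 8 mm slices at 2 mm
in-plane by default, slices ordered base → apex over the full myocardial
z-extent (the epicardial apex extends ~t0 below the endocardial apex; using
the cavity length instead would lose the apical cap, ~3% of shell volume).
A voxel is myocardium when its centre lies between the surfaces, decided per
slice with point-in-polygon tests against the meshes' section polygons.
Contours are recovered from mask boundaries by marching squares at level
0.5 — the delineation workflow run in reverse — with the larger loop as
epicardium and the inner loop as endocardium. Loops with fewer than 8 points
are dropped; that is legitimate only for the tiny epicardial cap in the
apex-most slice, so a degenerate non-apex slice, or a basal slice whose
cavity cannot be resolved, raises a resolution error.

## Template personalization

`fit_template()` substitutes a deliberately simple, fully reproducible
algorithm for high-order deformable-mesh frameworks: the statistical
pipeline only needs corresponded point sets, not smooth parametric meshes.

1. **Initialization** (optional): centroid translation, long-axis alignment
   from principal axes, isotropic scale from RMS radii; the long-axis sign
   and the in-plane rotation (16 candidates) are chosen by a coarse
   nearest-boundary cost. In-plane registration of a *near-axisymmetric*
   ventricle is intrinsically ill-posed; asymmetric features (septal bump,
   LVOT narrowing) are what anchor it.
2. **Iteration**: each node is projected along its surface normal onto its
   nearest corresponding boundary point (endo nodes to inner contours, epi
   to outer); the *displacement field* is relaxed by one grid-Laplacian pass
   with weight λ = 0.3 and applied; stop when the mean applied displacement
   falls below 0.05 mm (default `max_iter` 100).

Smoothing the displacement field, rather than the node positions, matters:
position smoothing contracts the grid tangentially on every pass, the normal
projection cannot undo tangential motion, and the iteration slides without
converging. With displacement smoothing the map is a contraction — fits
converge in ~5–15 iterations, a 1 mm voxelization round-trips to ~0.3 mm
nodal error, and the surface-to-contour error decreases with finer voxels.

Accuracy is reported as the distance from every contour point to the
matching triangulated surface (`fitting_error()`); on 2 mm voxelizations of
known synthetic anatomies the mean error is well under half the in-plane
resolution. The base plane and long axis of a fitted mesh are standardized
by the template fit itself (no independent landmarking), a choice the
downstream Procrustes alignment makes largely irrelevant.

Wall thickness is measured by casting each endocardial node's outward normal
ray onto the epicardial surface, averaging with the symmetric epi→endo
measurement when both are defined; rays that miss produce per-node missing
values, which are excluded from AHA segment means (an error is raised if
more than 10% of nodes are missing).

## The shape model

* **Pose normalization**: generalized Procrustes with translation and
  rotation only. No scaling — LV size and length are disease signal and must
  stay in the model; the leading mode is expected to capture them.
* **PCA** by SVD of the centred data matrix (equivalent to the covariance
  eigendecomposition with divisor n − 1, and numerically safer when the
  shape dimension ≫ n); all min(3M, n − 1) modes are retained.
* **Determinism**: eigenvector sign is arbitrary, so each mode's coordinate
  of largest absolute loading is made positive; eigenvalue ties keep SVD
  order. Repeated fits are bit-identical.
* **Mode inclusion**: the smallest K whose cumulative explained variance
  reaches the threshold (default 0.90), *inclusive* at the boundary — a
  cumulative ratio of exactly 0.90 qualifies (with a 1e−9 float guard).
* **Interface to the discriminant**: standardized coefficients (per-mode SD
  units), which makes "±3 SD" and Z-scores well-defined quantities.

## The discriminant axes

Fisher LDA weights solve `Sw w = mu_B - mu_A` with `Sw` the pooled
within-class covariance of the included standardized coefficients.

* **Regularization**: shrinkage toward scaled identity exists to guard
  against many modes vs small groups. The default (`"auto"`) therefore
  engages a Ledoit–Wolf intensity *only* when the problem is sample-starved
  (n ≤ p + 2) or `Sw` is numerically near-singular; otherwise the plain
  solve is used, because identity-target shrinkage measurably biases the
  axis away from the Fisher optimum on well-conditioned anisotropic data.
  Always-on Ledoit–Wolf (`"lw"`), a fixed γ, or 0 are available.
* **Z-scores** are normalized by the *pooled* training score mean and SD
  (both groups together), giving one axis with mean 0 / SD 1 over the
  training cohort, and are applicable unchanged to external subjects.
* **Orientation**: the sign is fixed so positive Z is the obstructive-like
  (or genotype-positive) group; only the direction and the continuous Z are
  used — no classification threshold, equal class priors implicit.
* **Extreme shapes** are anchored so their re-projected Z-scores are exactly
  ±k: coefficients move along the unit weight direction by
  `(score_mean ± k · score_sd) / ||w||`. When the axis is trained on the
  full PCA cohort the training score mean is 0 and the extremes straddle the
  mean shape exactly; on subgroup axes (e.g. the stress pair) the anchor is
  the axis's own Z = 0 point.
* **Validation**: AUC in the Mann–Whitney form (ties count ½), in
  resubstitution and leave-one-out. LOO refits the LDA (weights and
  normalization) per fold but holds the PCA fixed — the shape atlas is
  treated as population infrastructure, the axis as the estimate under test.
  Folds that would lose a class are skipped with a warning.
* **Per-mode screening** uses two-tailed pooled-variance t-tests at
  α = 0.05 with no multiplicity correction by default (mirroring per-mode
  screening as typically reported); a Bonferroni option is exposed.

`run_study()` orchestrates the three axes (rest, Δstress, genotype), the
50 mmHg severe-threshold refit and the paired-subset rest variant (each
summarized by its angle to the main rest axis), genotype projections on the
obstruction axes, Z-score tables, extreme-shape AHA maps and LVOT sector
areas, and a manifest; given an output directory it writes CSV/JSON/VTK with
MD5 hashes. The analysis contains no randomness beyond the cohort seed, so
reruns are bit-identical.

## Numerical choices and degenerate inputs

* Procrustes convergence: mean consensus change < 1e−6 mm; rotations by
  Kabsch/SVD with determinant correction (proper rotations only).
* Apex pole: the apex grid row is degenerate (all nodes coincide); its
  normals fall back to the transmural direction and zero-area triangles are
  excluded from ray casting and distance queries.
* Identical group means (‖δ‖ < 1e−12) → degenerate-separation error; zero
  pooled variance in a mode → t = 0, p = 1 with a warning; single-class AUC
  input → error.
* Truncated-normal parameter draws (±3 SD) with bounded retries prevent
  invalid geometries; an invalid draw (non-positive wall thickness,
  surfaces crossing) is redrawn, and exhaustion of the retry budget is an
  error rather than a silent fallback.
* Geometry validity is checked after construction: the epicardium must lie
  strictly outside the endocardium everywhere.

## Known limitations

* The synthetic spectrum is low-rank; conclusions about how many modes a
  real cohort needs, or about absolute AUC levels, do not transfer.
* The template fitter recovers surfaces, not anatomy: circumferential
  registration rests on shape asymmetry, and very symmetric ventricles may
  be registered with a rotated correspondence.
* The effective LVOT sector area is a geometric surrogate measured on the
  endocardial sector, not a flow computation.
* `project_external()` assumes the external meshes share the training
  template topology; cross-template studies are out of scope.
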