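---
title: "Vascular deformation mapping: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular deformation mapping: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Thoracic aortic aneurysms are monitored by serial CT angiography (CTA), and
the standard quantity — maximal aortic diameter measured manually in planes
orthogonal to the vessel axis — carries measurement variability of the same
order as typical annual growth. Vascular deformation mapping (VDM) replaces
the one-dimensional diameter with a three-dimensional description: a
deformable registration aligns the baseline ("fixed") and follow-up
("moving") CTA volumes, the resulting displacement field warps a triangular
mesh of the baseline aortic wall onto the follow-up anatomy, and growth is
read off the corresponding meshes as

* **AR**, the per-face *area ratio* `S(warped face) / S(fixed face)`
  (dimensionless, 1 = no areal change), and
* **DiN**, the per-vertex *deformation in the normal direction*: the signed
  projection of the vertex displacement onto the outward fixed-surface
  normal, in millimeters. The registration literature writes this
  projection with the opposite sign; `vdmkit` defines outward growth as
  positive, matching how the maps are read.

Because no clinical data set comes with ground-truth growth, the package
also implements a complete synthetic validation loop: parametric aortic
phantoms with *analytically known* deformation, a ground-truth displacement
field synthesized exactly the way the measured field will be extracted, and
perturbation experiments that degrade the images the way clinical
acquisition does.

## The registration pipeline

`runVDM()` composes three stages.

1. **Rigid alignment** (`rigidStage`): a 6-parameter transform (per-axis
   Euler rotations about the fixed-mask centroid plus translation)
   maximizing normalized cross-correlation (NCC). Initialization from the
   mask-centroid offset gives the stage a capture range far beyond any
   realistic patient repositioning. The metric is evaluated, by default,
   over the *background* — the complement of the dilated aortic masks of
   both frames. This choice decides what "patient position" means: when
   the whole scene moves (a table/position change) the background moves
   with it and the rigid stage follows; when only the aorta moves
   (respiration) the background stays put and the rigid stage correctly
   refuses to follow, leaving the physiologic displacement to the
   deformable stages. Evaluating NCC on or around the vessel instead would
   let the aorta — whose contrast dwarfs everything near it — drag the
   alignment along with its own motion, silently deleting that motion from
   the measured deformation.
2. **Centerline alignment** (`centerlineAlignmentStage`): a cubic B-spline
   free-form deformation (10 mm control spacing) driven by Parzen-window
   mutual information (MI) with a bending-energy penalty of weight 10 and a
   rigidity penalty of weight 20 on the dilated-mask coefficient map. The
   rigidity penalty (linearity, orthonormality and properness of the local
   Jacobian) lets surrounding tissue deform while the aorta itself moves
   near-rigidly, implicitly aligning the aortic centerlines — this is the
   stage that absorbs respiratory displacement of the vessel. It is seeded
   with the residual mask-centroid offset as a constant (penalty-free)
   B-spline translation, because respiratory-scale displacement can exceed
   the optimization's blind capture range.
3. **Final deformable stage** (`finalDirStage`): a finer B-spline (6 mm
   control spacing) with MI and a stronger bending weight of 100, capturing
   the local wall deformation that constitutes growth.

The field handed to the growth metrics is the composition of the two
*deformable* stages, expressed on the fixed grid in rigid-normalized moving
space. The rigid transform itself is deliberately excluded: bulk patient
repositioning is alignment, not growth, and folding it into the field would
let a 40 mm table shift masquerade as wall displacement. It travels in the
field's metadata, and `runVDM(..., includeRigid = TRUE)` composes it back
for resampling the raw moving image.

### Numerical design of the optimizer

No registration backend exists in this R stack, so the B-spline transform,
both similarity metrics, both penalties and their analytic gradients are
implemented natively (C++ via Rcpp) and optimized with L-BFGS-B over two
image-resolution levels (smoothed/strided first, then full resolution).
Three choices matter for accuracy and are worth recording:

* **Boundary-shell sampling.** Similarity samples are drawn from a shell
  around the segmented wall (half-width 12 mm for the centerline stage,
  which needs capture range; 4 mm for the final stage). All alignment
  information lives at the wall; flat-background samples contribute only
  their noise to the MI histogram, and removing them measurably reduces
  both clean-image wobble and noise-induced error.
* **Sub-voxel sample jitter.** Sample positions are perturbed uniformly
  within a voxel (fixed seed). With on-grid samples and linear
  interpolation, the variance of interpolated image noise depends on the
  fractional part of the transform, which locks the optimum onto the voxel
  lattice; jitter removes the artifact for both the NCC and MI stages.
* **Replicate averaging.** At the finest level each deformable stage is
  solved on (by default 2) disjoint similarity-sample subsets from the same
  warm start and the control coefficients are averaged. Each solution
  carries the same anatomy but a partially independent imprint of image
  noise, so the average suppresses noise-fitting without the cost of a
  stochastic-gradient optimizer.

MI uses 48 histogram bins (linear window on the fixed intensities, cubic
B-spline window on the moving ones). Compared to the conventional 32 bins,
the sharper joint histogram halves the small spurious deformation that the
estimator's finite-sample gradient otherwise produces even for identical
images; self-registration then satisfies `|AR - 1|` below 0.02 and `|DiN|`
below 0.1 mm at the 99th percentile, the scale at which all field-level
statements in the package are made.

## Synthetic phantoms

`phantomSpec()` describes a candy-cane tube — ascending limb (45 mm,
long enough that a 30 mm growth patch sits on intact wall away from the
proximal cut plane), a semicircular arch (radius 25 mm) and descending
limb (60 mm), lumen radius 12 mm — swept with rotation-minimizing frames
so the angular coordinate is twist-free. The rasterizer fills the capped
tube by supersampled parity ray-casting (exact through-plane interval
coverage), mapping occupancy to a 350 HU lumen on a 40 HU soft-tissue
background with partial-volume antialiasing at the wall; the binary mask
thresholds occupancy at 0.5. The background carries smooth random
heterogeneity (35 HU standard deviation, 8 mm correlation length,
`intensityModel`) standing in for the mediastinal fat/muscle mosaic — it
is what gives the background-domain rigid stage something static to hold
on to, exactly as thoracic anatomy does clinically. An optional
`wallIrregularity` perturbs the lumen radius with a smooth random pattern
(real aortas are not surfaces of revolution); it is off by default because
the analytic-recovery checks below are sharpest on exact surfaces of
revolution, but it measurably improves the identifiability of tangential
motion in the respiratory experiment and is worth enabling when that is
the question under study.

Three deformation operators replace interactive mesh sculpting, so ground
truth is analytic and reproducible:

* `applyRadialBulge` — fusiform growth: outward displacement along the
  local radial direction, modulated by a compactly supported cosine-squared
  bump in arc length;
* `applySculptBulge` — saccular growth: the same, restricted to an angular
  sector by a second cosine-squared window;
* `applyDrag` — rigid translation of an arc-length interval blended
  smoothly to zero, emulating respiratory displacement and bending.

All operators preserve vertex count and order (correspondence is
positional) and accumulate their exact displacement in the mesh metadata.
The cosine-squared window was chosen because it is C1, exactly zero outside
its support, and produces the smooth fusiform/saccular shapes seen
clinically.

The desk-scale studies rasterize at 1.25 x 1.25 x 1.0 mm on roughly
80 x 40 x 120 voxel volumes. This is deliberately coarser than clinical CTA
(0.64 x 0.64 x 0.75 mm, ~230 x 230 x 440 voxels, which the generator also
supports) so that a ten-phantom population with all perturbation arms runs
on one CPU in tens of minutes; consequences of the coarser grid are noted
under *Limitations*.

## Ground-truth synthesis

Warping the fixed mesh by the *measured* field and comparing against the
*analytically* deformed mesh would mix two error sources: the
registration's own error and the gap between any image-supported field and
the analytic vertex motion. The validation instead declares as ground truth
a field extracted from images the same way the measurement will be:

1. corresponding fixed and deformed meshes are converted to binary
   *boundary images* (voxels containing surface points set to one) and
   blurred (Gaussian, sigma 2 voxels);
2. a single-stage B-spline registration (8 mm control spacing, mean-squared
   difference on range-normalized intensities, bending weight 0.5,
   seeded with the mesh-centroid offset for capture range) aligns them,
   with the deformed boundary as the fixed image;
3. that transform can resample the fixed CT and mask into a synthetic
   moving image and mask (`makeGroundTruth`'s pull-back outputs), and its
   numerical inverse (fixed-point iteration) is the declared ground-truth
   field in the package's fixed-to-moving convention, so one field warps
   the fixed mesh onto the anatomy of the moving frame.

The packaged studies build the moving image slightly differently: they
rasterize the *deformed mesh* over the same static textured background as
the fixed image (`rasterizeMesh`), rather than warping the fixed CT. The
two routes agree at the vessel wall to within the step-2 registration
error (their masks overlap with Dice above 0.98), but they say different
things about the background: the warped construction drags the
surroundings along with whatever the B-spline extrapolates — including a
zero-bending-cost constant translation of *all* distant tissue when the
aorta is displaced bodily — whereas in reality (and in the rasterized
construction) only the vessel and its immediate neighborhood move. A
static background is what the rigid stage needs to distinguish patient
repositioning from aortic physiology, so the rasterized moving image is
the study default; the price is that the step-2 registration error now
enters the ground-truth-versus-measurement comparison on both sides, as
it does in the clinical setting.

Two implementation details depart from the obvious construction, both
because the obvious construction is measurably biased:

* **Surface-saturated boundary images.** Using mesh vertices alone imprints
  the vertex density on the boundary image; a stretched (grown) surface is
  then dimmer, and the least-squares optimum systematically under-estimates
  the growth. `makeGroundTruth` therefore subsamples every face below half
  the voxel pitch before binarization, which saturates the one-voxel shell
  identically in both images. The plain vertex-occupancy operator remains
  available (`meshToBoundaryImage` with `maxEdge = NULL`).
* **Blur scale.** Sigma is specified in voxels on the boundary-image grid;
  at the desk-scale grid, 2 voxels (2-2.5 mm) matches the physical blur
  the clinical-resolution setting implies and minimizes the blur-induced
  shrinkage of large bumps. Heavier blur measurably biases the recovered
  bump amplitude (the pulled-back shell is anisotropically stretched where
  the deformation has strain, and the bias grows with sigma).

On the default phantoms the round trip — warp the fixed mesh with the
synthesized field, compare against the analytic deformation — agrees to a
99th-percentile vertex error below 0.5 mm for bump magnitudes around
2.5 mm. For larger bumps (5 mm) the *normal* component stays within about
0.5 mm, but the *tangential* component can deviate by ~1 mm: a smooth
featureless surface simply does not determine tangential motion (the
aperture problem), and bending regularization, not data, picks it.
The growth metrics are normal-dominated, and the measured field is always
compared against the declared GT field (whose moving image it explains), so
this indeterminacy cancels from the validation loop; it is why the field,
not the analytic motion, is the declared truth. For the same reason the
respiratory drags are only partially visible in the boundary images (a tube
translated along its own axis maps onto itself except at the arch and
ends); the synthetic moving image remains exactly concordant with the GT
field by construction.

## Perturbation experiments

`runRobustnessExperiment` perturbs the images entering registration — never
the ground truth — and reports, per phantom and level, the 99th-percentile
absolute AR/DiN errors in the deformed region (|GT DiN| > 0.01 mm) and the
relative error `(err_perturbed - err_original) / GT 99th percentile` in
percent.

* **Noise**: i.i.d. Gaussian noise added to both images, with sigma
  calibrated so the contrast-to-noise ratio (aortic ROI = mask eroded by 3
  voxels; background ROI = an automatic 6-18 mm shell standing in for
  manually drawn mediastinal-fat ROIs) hits the target levels 6.84, 3.88
  and 2.66. Calibrating by CNR rather than raw sigma makes the levels
  transferable between the synthetic and clinical intensity scales.
* **Slice thickness**: box-average (slice-sensitivity-profile) resampling
  along z to 1.0, 1.5 and 2.0 mm, images and masks alike.
* **Bulk motion**: one random rigid motion per pair (per-axis rotations
  uniform in +/-5 degrees; translation of magnitude 20/40/60 mm with random
  per-axis signs) applied to the moving image and mask, with the output
  grid padded so no anatomy leaves the field of view. Cubic interpolation
  is used so the perturbed arm is not additionally blurred relative to the
  baseline arm.

The respiratory arm (`runRespiratoryStudy`) builds six phantoms combining
growth (1.5-6.5 mm, ascending and descending) with drags of the
ascending-through-proximal-descending segment. The drag vectors (3-8 mm,
predominantly cranio-caudal) follow the magnitudes reported for
inspiration-to-expiration aortic displacement. These phantoms use a longer
geometry (60 mm ascending, 120 mm descending limb), mirroring the clinical
field of view that runs from above the arch to the upper abdomen: most of
the descending aorta lies distal to the dragged segment, so static
anatomy anchors the rigid alignment the way the spine and abdominal
organs do in patients. Errors are summarized as 99th percentiles across
*all* vertices, and the respiration-attributable increase is the
difference against the same phantom analyzed without the drag.

## Diameter analysis

`extractCenterline` computes the interior distance transform, finds the
object's ends by geodesic sweeps, links them with a minimal path weighted
to hug the maximal-inscribed-sphere ridge, trims the path ends by 1.6 times
the maximal inscribed radius (the scale over which the path transitions
from the end-cap rim to the axis), and smooths with per-coordinate
smoothing splines resampled at 0.5 mm. `diameterProfile` cuts the mesh with
the plane orthogonal to the tangent at every station, chains the
intersection segments into closed contours (so that a plane slicing both
limbs of the candy-cane picks the local one), and takes the maximal chord
of the contour — the convention behind "maximum diameter" in aortic
measurement; stations with ill-defined sections are flagged rather than
fatal. The VDM-based measurement warps the fixed mesh with the registration
field and profiles it against the *same* fixed centerline, so diameter
change reflects wall motion, not centerline motion.

## What the tests show — and what they cannot

The property suite is exact: metric identities (AR under scaling, DiN under
dilation and tangential slide), penalty zeros (affine fields for bending,
rigid motions for rigidity) and closed forms (isotropic scaling), the CNR
formula, NCC invariances, and percentile summaries against sort-based
oracles. The integration suite exercises the entire chain on generated
phantoms: ground-truth concordance, a ten-phantom population study,
robustness arms, the respiratory arm, and diameter-change localization
against a random-station baseline.

Passing these tests shows the measurement chain is internally consistent
and accurate *for tube-like phantoms with smooth parametric deformations on
clean synthetic images*. It does not show performance on real CTA:
phantoms lack branch vessels, calcification, wall thickening, contrast
heterogeneity, cardiac-phase pulsation and reconstruction texture, and the
deformations are smoother than biological growth. Gaussian noise is not CT
noise (no spatial correlation from the reconstruction kernel).

### Why the respiratory numbers are the hardest

A drag blends from full translation to rest somewhere along the straight
descending limb. In that blend zone the deformation is an axial shear of
a smooth tube — motion *along* the surface, which no image or boundary
information can determine (the aperture problem again). The declared
ground truth and the measurement each fill that null space with their own
regularizer, and the area ratio, which is sensitive to tangential
stretch, pays for the disagreement: the respiratory-arm AR and DiN error
increases measured here run several-fold above what was reported on
phantoms derived from real CTAs, whose branch ostia and wall irregularity
pin the tangential motion. Enabling `wallIrregularity` recovers part of
that identifiability (the drag-case DiN error roughly halves in our
measurements) at the cost of the analytic-recovery checks, which assume a
surface of revolution. The mean absolute DiN error across the six
respiratory phantoms is at the clinically reported scale either way; the
99th-percentile statistics are where the indeterminacy concentrates.

## Known limitations

* The desk-scale grid (about 1.25 mm vs 0.64 mm clinically) doubles the
  per-volume noise dose at matched per-voxel CNR (noise power scales with
  sigma^2 times voxel volume) and roughly doubles all voxel-limited error
  floors. The noise-arm relative errors are therefore several-fold larger
  than would be measured at clinical resolution, while the slice-thickness
  and bulk-motion arms, which are not noise-limited, are at the clinical
  scale.
* Tangential surface motion is underdetermined for smooth tubes (see
  above); the ground truth is only as tangentially meaningful as its
  regularizer, and respiratory-arm 99th-percentile statistics inherit
  that indeterminacy.
* Grids are axis-aligned (identity direction matrices); rotated acquisition
  geometries must be resampled upstream.
* The rigidity penalty evaluates its coefficient map at the fixed-space
  position rather than the displaced position; for the binary dilated mask
  and millimeter-scale displacements the difference is immaterial.
* Single connected, unbranched vessels only; the aortic root / sinuses are
  out of scope, as is cardiac-phase (pulsatile) deformation.
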