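# vdmkit

Quantifying three-dimensional growth of the thoracic aorta from serial
CT-angiography-like volumes by **vascular deformation mapping (VDM)** — and
validating the whole measurement chain on synthetic phantoms with known
ground truth.

## Who this is for

Researchers in vascular image analysis who want either (a) a
self-contained, dependency-light R implementation of regularized B-spline
deformable registration with mesh-based growth read-out, or (b) a
reproducible harness for studying how image quality (noise, slice
thickness, patient motion, respiration) propagates into growth-measurement
error.

## The method

Given a baseline ("fixed") and follow-up ("moving") volume with aortic
segmentation masks, `runVDM()` estimates the wall deformation in three
stages:

1. **rigid alignment** maximizing normalized cross-correlation
   (Ω restricted to the dilated aortic mask):
   `NCC = Σ (I_F - Ī_F)(I_M∘T - Ī_M) / sqrt(Σ (I_F - Ī_F)² Σ (I_M∘T - Ī_M)²)`
2. **centerline alignment**: cubic B-spline transform minimizing
   `-MI + 10·P_bend + 20·P_rigid`, where `P_bend` is the mean squared
   Frobenius norm of the transform's second spatial derivatives and
   `P_rigid` penalizes deviation of the local Jacobian from a rigid motion
   (linearity + orthonormality ‖JᵀJ−I‖² + properness (det J − 1)²) on the
   dilated-mask coefficient map — tissue around the aorta may deform, the
   aorta itself moves near-rigidly;
3. **final deformable registration**: a finer B-spline minimizing
   `-MI + 100·P_bend`.

The composed deformable field warps the fixed-surface mesh
`V = {v_i}` onto the moving anatomy, `v̂_i = v_i + u(v_i)`, and growth is
quantified per element:

- **area ratio** `AR_f = S(f{v̂_i,v̂_j,v̂_k}) / S(f{v_i,v_j,v_k})`
- **deformation in normal direction** `DiN(v_i) = n⃗(v_i) · (v̂_i − v_i)`
  (mm; outward growth positive)

The phantom side generates candy-cane aortic tubes, applies parametric
growth (fusiform bulges, saccular sculpting, respiratory drag) with exact
vertex correspondence, rasterizes CT-like volumes, and synthesizes a
ground-truth displacement field by registering blurred boundary images of
the fixed and deformed surfaces — so the synthetic moving image and the
ground-truth field are exactly concordant.

## Worked example

```r
library(vdmkit)

# a descending-aorta fusiform growth phantom, 2.5 mm peak magnitude
ph <- makeStudyPhantom("descending", "radial", 2.5, seed = 2)

# ground truth: boundary-image registration + synthetic moving image
gt <- makeGroundTruth(ph$fixedMesh, ph$deformedMesh, ph$image, ph$mask)

# the full three-stage VDM registration
field <- runVDM(ph$image, gt$movingImage, ph$mask, gt$movingMask)

# growth metrics and their error against ground truth
vdmMesh <- warpMesh(field, ph$fixedMesh)
gtM  <- computeGrowthMetrics(ph$fixedMesh, gt$gtMesh)
vdmM <- computeGrowthMetrics(ph$fixedMesh, vdmMesh)
growthAbsoluteError(gtM, vdmM, ph$fixedMesh, threshold = 1e-3)$summary
#>   metric    n        p99        p95      median       mean         sd threshold
#> 1     AR 6480 0.04556577 0.02853757 0.004837661 0.00742683 0.00925113     0.001
#> 2    DiN 3078 0.09443066 0.07063808 0.028550067 0.03297470 0.02533487     0.001
```

The summary says: within the deformed region (ground-truth |DiN| above
0.001 mm), half of all vertices recover the normal wall displacement to
better than 0.03 mm and 99% to better than 0.10 mm; area ratios are
recovered to 0.005 (median). A self-registration (`moving = fixed`) gives
`AR ≡ 1` within 0.02 and `DiN ≡ 0` within 0.1 mm at the 99th percentile.

Higher-level drivers reproduce whole experiments:

```r
pop  <- runPopulationStudy(nPhantoms = 10, seed = 1, keepData = TRUE)
rob  <- runRobustnessExperiment(pop)     # noise / slice thickness / bulk motion
resp <- runRespiratoryStudy(seed = 1)    # growth + respiratory drag
```

A thin command-line front end for shell pipelines lives at
`inst/cli/vdmkit.R` (subcommands `phantom`, `gt`, `register`, `metrics`,
`perturb`, `diameter`, `experiment`).

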