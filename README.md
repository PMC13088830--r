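# canalseg

Micro-CT-guided tooth and root canal segmentation from cone-beam CT
(CBCT), as an end-to-end testable R package.

Clinical CBCT (80-200 µm voxels) blurs exactly the anatomy that endodontic
planning needs — apical canal segments, accessory canals, isthmuses —
while ex vivo micro-CT (~30 µm) resolves them with enough contrast that a
single threshold segments the whole canal system. `canalseg` implements
the training strategy built on that asymmetry: threshold the micro-CT of
an extracted tooth into tooth + canal masks, register them rigidly onto
the paired CBCT scan, and use the transferred masks as high-fidelity
ground truth to train a CBCT segmentation network, in two cascaded stages
(tooth first, then the canal inside the predicted tooth).

Because no public paired micro-CT/CBCT dataset exists, the package ships a
synthetic phantom generator producing paired renderings of parameterized
teeth (crown, 1-3 tapered roots, tapering and optionally curved canals,
accessory canals, isthmuses, C-shapes) with known ground truth, plus a
"manual annotation" degrader for control-arm comparisons. Everything —
geometry, registration, network, metrics — runs deterministically from
seeds on one CPU.

## What is inside

* `volume3d` / `binary_mask`: isotropic 3D volumes with world geometry,
  NIfTI I/O (RNifti), cropping, trilinear/nearest resampling.
* `phantom_spec`, `generate_tooth`, `simulate_cbct`, `degrade_labels`,
  `generate_cohort`: the synthetic study conditions.
* `threshold_uct`, `icp_register`, `transfer_labels`,
  `groundtruth_fidelity`: micro-CT-guided label generation (trimmed rigid
  ICP with closed-form SVD alignment).
* `net_config`, `build_model`, `train_stage`, `segment_tooth`,
  `segment_canal`: a nested-U (residual-U-block) segmentation network with
  deep supervision, implemented natively with RcppArmadillo kernels, in
  `tiny` (~28k parameters) and `full` configurations.
* `overlap_metrics`, `surface_deviation`, `compare_arms`: Dice (DSC),
  sensitivity (SEN), intersection-over-union (IOU)

  DSC = 2|V_gt ∩ V_seg| / (|V_gt| + |V_seg|),
  SEN = |V_gt ∩ V_seg| / |V_gt|,
  IOU = |V_gt ∩ V_seg| / |V_gt ∪ V_seg|,

  and signed surface-deviation analysis.
* `connected_components`, `remove_false_positives`: post-processing of
  canal predictions (keep-largest, minimum-size, keep-in-region policies).
* `run_arm_experiment`, `run_resampling_experiment`, `repro_run`: the
  bundled experiments, and `canalseg_main()` + `inst/cli/canalseg` as a
  command-line front end (`phantom | labelgen | train | segment |
  evaluate | postprocess | repro`).

## Worked example

```r
library(canalseg)

spec <- phantom_spec(tooth_class = "SR", root_length = 4.5,
                     canal_curvature = 0.4, accessory_canal = TRUE,
                     seed = 11)
tooth <- generate_tooth(spec)
tooth$uct
#> <volume3d> 154 x 154 x 235 voxels @ (0.03, 0.03, 0.03) mm, origin (-2.3, -2.3, -0.3) mm

# micro-CT thresholding recovers the canal system exactly on the phantom
masks <- threshold_uct(tooth$uct, "global", value = 550)
overlap_metrics(tooth$canal_gt, masks$canal)
#> DSC 1.0000  SEN 1.0000  IOU 1.0000  (|gt| 73731, |seg| 73731)

# simulate an 80 um CBCT under a rigid pose offset, then recover the pose
# by ICP and transfer the labels onto the CBCT grid
pose <- rigid_transform(euler_rotation(c(3, -2, 5)), c(0.4, -0.2, 0.3))
cbct <- simulate_cbct(tooth$uct, target_voxel = 0.08, noise_sd = 50,
                      pose = pose, seed = 11)
lab <- uct_guided_labels(tooth$uct, cbct, threshold_value = 550)
lab$rms
#> ICP residual: 0.095 mm

# transferred canal label vs the true-pose transfer
overlap_metrics(transfer_labels(tooth$canal_gt, pose, cbct), lab$canal)
#> DSC 0.9480  SEN 0.9479  IOU 0.9011  (|gt| 3893, |seg| 3892)

# ground truth itself degrades as the target grid coarsens
groundtruth_fidelity(tooth$canal_gt, c(0.04, 0.08, 0.2))
#>   target_voxel       dsc
#> 1         0.04 0.9841040
#> 2         0.08 0.9611583
#> 3         0.20 0.8921904
```

The first block shows thresholding is exact at micro-CT resolution on the
phantom (DSC 1.0); the ICP residual of ~0.1 mm is about one CBCT voxel of
surface discretization; the transferred canal label agrees with the
true-pose transfer at DSC 0.95; and the fidelity table shows the mechanism
behind resolution effects — the same canal mask keeps 98% Dice after a
round trip through a 40 µm grid but only 89% through 200 µm, so the ground
truth itself is resolution-dependent.

Training the tiny cascade end to end on phantoms is a few minutes per
stage on one CPU; see `?train_stage`, `?run_arm_experiment` and the
methods vignette (`vignettes/canalseg-methods.Rmd`) for the experiment
designs and their assumptions.

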