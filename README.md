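# dirdose

Deformable-registration (DIR) based dose accumulation for cervical-cancer
radiotherapy courses that combine external-beam radiotherapy (a whole-pelvis
plan plus a center-shielded plan with a 4 cm midline block) with weekly
high-dose-rate intracavitary brachytherapy — and its comparison against the
clinically standard GEC-ESTRO-style *DVH parameter addition*.

## Who this is for

Medical-physics researchers who want to study, on fully controlled synthetic
pelvic phantoms with known ground-truth deformations, how registration
accuracy propagates into accumulated organ-at-risk dose metrics
(D<sub>0.1</sub>, D<sub>1</sub>, D<sub>2</sub> cm³ of rectum and bladder),
and when the hotspot-co-location assumption behind DVH parameter addition
breaks down.

## What it computes

* **Synthetic phantom courses** — a reference brachytherapy CT frame with an
  intracavitary applicator, further BT frames with inter-fraction
  organ-filling changes, an applicator-free EBRT frame with a rigid pose
  offset, per-plan doses (inverse-square dwell sums normalized so the
  HR-CTV D90 equals the 6 Gy prescription; whole-pelvis box; AP/PA
  center-shielded dose), and the exact generative deformation fields.
* **Registration** — automated rigid uterus fusion, then deformable
  registration in the two clinical parameter settings:
  *intensity-based* (image similarity in the body only) and *hybrid*
  (image similarity + soft-Dice matching of uterus/rectum/bladder/body
  contours), minimizing
  `E(u) = w_img·S_img + w_struct·S_struct + w_reg·R(u)`
  by monotone multi-resolution gradient descent. Accuracy is scored with the
  Dice similarity coefficient `DSC = |V_d ∩ V_s| / ((|V_d|+|V_s|)/2)` and,
  against the stored ground truth, a surface target registration error.
* **Dose accumulation** — voxel-wise EQD2 conversion
  (`EQD2 = D·(d + α/β)/(2 + α/β)`, α/β = 3 Gy), warping of every plan's dose
  to the reference frame, summation, and hottest-subvolume metrics from
  exact voxel sorting; plus DVH parameter addition (center-shielded plans
  excluded, per the clinical rule) for comparison, in both scopes
  (BT only; BT + EBRT).

## Worked example

```r
library(dirdose)

course <- generate_phantom_course(seed = 1)   # ~0.6 M voxel case, 6 frames
report <- run_course(course)                  # few minutes on one core
report
```

Output (computed by the code above):

```
<accumulation_report> seed 1, scopes: BT_only, BT_plus_EBRT
          scope   organ metric_cm3 intensity_dir hybrid_dir addition
1       BT_only  rectum        0.1         5.522      5.521    5.564
2       BT_only  rectum        1.0         4.840      4.850    4.886
3       BT_only  rectum        2.0         4.453      4.449    4.488
4       BT_only bladder        0.1         5.279      5.506    5.553
5       BT_only bladder        1.0         4.409      4.514    4.596
6       BT_only bladder        2.0         3.978      4.045    4.132
7  BT_plus_EBRT  rectum        0.1        35.522     35.521   35.564
8  BT_plus_EBRT  rectum        1.0        34.840     34.850   34.886
9  BT_plus_EBRT  rectum        2.0        34.453     34.449   34.488
10 BT_plus_EBRT bladder        0.1        52.038     51.970   35.553
11 BT_plus_EBRT bladder        1.0        51.358     51.537   34.596
12 BT_plus_EBRT bladder        2.0        49.285     51.072   34.132

Mean DSC by method:
     method mean_dsc
1    hybrid    0.977
2 intensity    0.878
3     rigid    0.861
```

How to read this: doses are Gy EQD2. In the BT-only scope the three methods
nearly agree, with DVH addition slightly above the DIR-based values — the
per-fraction hotspots shift with organ filling, so addition mildly
overestimates. In the BT + EBRT scope the rectum (entirely inside the
midline block) still agrees, but the accumulated bladder dose far exceeds
addition: the lateral bladder protrudes beyond the 4 cm block and collects
whole-pelvis *and* center-shielded dose there, which addition ignores by
design. The hybrid registration, which also matches the contours, clearly
outperforms intensity-only registration (mean DSC 0.98 vs 0.88). `tidy()`,
`glance()` and `autoplot()` give tibble and ggplot views of the report, and
`cohort_summary()` aggregates several seeded cases.

## Package layout

* `R/grid_model.R`, `R/transforms.R` — volumes, grids, NIfTI I/O, rigid
  transforms, displacement fields, warping.
* `R/phantom.R`, `R/dose_sim.R` — synthetic case generator and dose models.
* `R/registration.R` — rigid fusion, the DIR objective/optimizer, DSC, TRE.
* `R/dose_accumulation.R`, `R/dvh.R` — EQD2, accumulation, DVH metrics,
  DVH parameter addition.
* `R/pipeline.R` — `run_course()`, reports, cohort summaries.
* `vignettes/dose-accumulation-methods.Rmd` — the model, parameters,
  design decisions and limitations in detail.
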