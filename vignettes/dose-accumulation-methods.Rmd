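---
title: "Methods: DIR-based dose accumulation for combined EBRT and brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIR-based dose accumulation for combined EBRT and brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Locally advanced cervical cancer is treated with external-beam radiotherapy
(EBRT) — a whole-pelvis (WP) plan plus, at some institutions, a
center-shielded (CS) plan whose midline block spares the zone where the
rectum and bladder receive the highest brachytherapy dose — combined with
weekly high-dose-rate intracavitary brachytherapy (BT) boosts prescribed to
the HR-CTV D90. The clinically standard way to report the cumulative dose to
the organs at risk is *DVH parameter addition*: each plan's hottest-subvolume
dose (D$_{0.1}$, D$_1$, D$_2$ cm³), converted to the equivalent dose in 2 Gy
fractions (EQD2), is summed across plans. This is exact only when the most
exposed subvolumes co-locate across all fractions.

The alternative is *DIR-based dose accumulation*: deform every treatment
frame onto a reference frame (the first BT CT) with deformable image
registration, warp the per-plan dose distributions through the estimated
fields, sum voxel-wise in EQD2, and extract the D$_x$ cm³ metrics from the
accumulated distribution. Its accuracy is bounded by the accuracy of the
registration, which is hard between EBRT and BT frames because the
intracavitary applicator deforms the uterus by centimetres.

This package implements both evaluation routes end to end and validates them
on synthetic pelvic phantoms with analytically known ground-truth
deformations — the kind of ground truth patient data cannot provide.

## Synthetic phantom

`phantom_spec()` defines a voxelized pelvic scene in world millimetres:
an elliptic-cylinder body (soft tissue, 35 HU), ellipsoidal uterus (45 HU)
and bladder (10 HU), a tubular rectum (25 HU), an HR-CTV around the cervix,
and a straight tandem applicator (3 mm radius, 3000 HU) in the uterine
canal. Interfaces are softened with a 1-voxel Gaussian and a seeded smooth
noise texture (SD 12 HU) is added so that intensity-driven registration has
realistic gradients to work with. The default grid is 96 × 96 × 64 voxels at
2.5 mm isotropic — under 10⁶ voxels, while still resolving the 4 cm midline
shield and the steep BT gradients.

`generate_deformed_frame()` derives the other treatment frames from the
reference by *pull-back* sampling: the new frame reads the reference at
`y + h(y)`, where `h` is built from closed-form components:

* **Organ filling** (BT fractions and the EBRT frame): radial scaling of the
  bladder (volume) and rectum (diameter) about the organ centre, with a
  smooth Gaussian falloff outside the organ. Default linear scale factors
  per frame: bladder 1.2 / 0.85 / 1.1 / 1.12, rectum 0.9 / 1.15 / 1.05 /
  0.95 — the plausible range of day-to-day filling change.
* **Applicator release** (EBRT frame only): a radial field about the tandem
  axis with profile $A\,(\rho/\lambda)\,e^{1/2-\rho^2/2\lambda^2}$ (peak
  amplitude $A = 10$ mm at $\rho = \lambda = 30$ mm), representing the
  relaxation of peri-canal tissue once the applicator is absent. Applicator
  voxels are replaced by uterine-tissue HU before warping.
* **Pose offset** (EBRT frame): a rigid 3° / 5 mm set-up difference composed
  with the deformation.

The composed field is smoothed (σ = 1 voxel) and its discrete Jacobian
checked; amplitudes that fold space are rejected. Because generation is a
pull-back, the *exact* generative field is stored with each frame without
any numeric inversion, and registration accuracy can be scored as the
composition residual $|T(x) + h(x + T(x))|$ (zero iff the estimated map
inverts the generative one) — reported by `registration_tre()` at
organ-surface voxels.

What the phantom does **not** emulate: CT texture and artefacts, bone and
gas, tumour regression, gauze packing, curved applicator geometry (ovoids),
and organ sliding. Passing tests on the phantom therefore demonstrate the
correctness and internal consistency of the pipeline and the *mechanisms*
of the method differences, not clinical registration accuracy.

## Dose models

* **BT**: inverse-square dwell sum, $d(v) = S \sum_i (r_0 / r_i)^2$ with
  $r_0 = 10$ mm, five dwells spaced 5 mm on the tandem axis, distances
  floored at half a voxel diagonal. $S$ is set so the HR-CTV D90 equals the
  prescription (6 Gy/fraction) exactly. No TG-43 anisotropy or radial dose
  function: the analysis only requires a sharp, applicator-centred gradient
  (the 30%-isodose volume is >4× the 90%-isodose volume).
* **WP**: a near-uniform box (±3%) with sigmoidal penumbra (50% at the field
  edge), total 30 Gy in 15 fractions.
* **CS**: the same box times a midline block factor — a 40 mm wide
  left-right strip reduced to `transmission`·total (default 0, i.e. a
  complete block; configurable to small positive values to mimic partial
  transmission), total 20 Gy in 10 fractions. WP + CS equal the 50 Gy EBRT
  course total.

## Registration

Every moving frame is first rigidly fused to the reference by maximizing the
uterus Dice overlap (`rigid_register()`; centroid initialization +
Nelder-Mead on a Gaussian-softened Dice objective, search bounded to ±20 mm
/ ±15°, never returned worse than the identity). The applicator HU are
replaced by −1000 HU on BT frames before deformable registration.

`deformable_register()` then minimizes

$$E(u) = w_\mathrm{img} S_\mathrm{img}(u) + w_\mathrm{struct}
S_\mathrm{struct}(u) + w_\mathrm{reg} R(u)$$

* $S_\mathrm{img}$: one minus the local normalized correlation of HU inside
  the body, implemented as the mean squared difference of locally
  standardized intensities (local mean/SD over a σ = 8-voxel window, SD
  floored at 30 HU — the floor keeps noise in flat regions from being
  amplified).
* $S_\mathrm{struct}$: mean over structures of one minus the soft Dice
  between the warped moving mask and the fixed mask (masks softened with a
  σ = 2-voxel Gaussian, which also sets the capture range).
* $R$: discrete bending energy (sum of squared second differences of the
  field components).

The two clinical parameter settings are expressed purely through the
configuration: *intensity-based* uses the body structure only and
$w_\mathrm{struct}=0$; *hybrid* adds uterus, rectum, bladder and body with
$w_\mathrm{struct}=1$. Defaults: $w_\mathrm{img}=1$, $w_\mathrm{reg}=0.1$,
3 pyramid levels (4× / 2× / 1×) with 100 / 100 / 50 iterations.

Optimization is a smoothed gradient descent (force smoothing σ = 2 voxels,
per-iteration displacement capped at 0.8 voxel) with *backtracking step
control*: a step is only accepted if the full objective decreases, so the
recorded objective trace is non-increasing within every level and the whole
procedure is deterministic (zero-field initialization, no randomness). The
descent direction uses the fixed-image gradient (as in classic demons
registration); the backtracking rule is what guarantees monotonicity of the
stated energy regardless of the direction's quality. This is a documented
surrogate for the commercial hybrid algorithm used clinically, whose
internals are unpublished; matching that implementation bit-for-bit is
explicitly not a goal — only the *class* of method (intensity-only vs
intensity + contours) is reproduced.

## Accumulation and metrics

`eqd2_convert()` applies the linear-quadratic conversion voxel-wise,
$\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$ with
$d = D/n_\mathrm{fractions}$ and $\alpha/\beta = 3$ Gy for the organs at
risk. Conversion happens in each plan's native frame *before* warping
(the LQ transform is nonlinear and should see the planned dose); the
opposite order is available via `accumulate_dose(..., eqd2_first = FALSE)`
and recorded in the provenance, since the clinical description does not pin
the order down. Plans are summed in canonical label order so the result is
bit-identical under permutation of the plan list.

`d_cc()` computes D$_x$ cm³ by exact descending voxel sort with
partial-voxel linear interpolation at the crossing — no histogram binning,
so the small 0.1 cm³ metric carries no bin-width sensitivity. The binned
`compute_dvh()` curve (default 0.1 Gy bins) exists for plotting and export
only. `d90()` is `d_cc` at 90% of the target volume.

`dvh_parameter_addition()` evaluates each plan on its *own* frame's organ
mask (as clinically contoured) and sums the included plans; CS plans are
excluded, mirroring the clinical rule that the midline block spares the
zone of highest BT dose. DIR-based accumulation, by contrast, uses the CS
dose — which is the interesting asymmetry: wherever an organ protrudes
laterally beyond the 4 cm block, the accumulated dose picks up WP + CS dose
that addition ignores. On the phantom this effect dominates the bladder in
the BT + EBRT scope (the lateral bladder receives the open CS field), so
DIR-based values exceed addition there — the same mechanism reported for
patients. The zero-deformation equality between the two evaluation routes
is therefore exact only on the addition-eligible plan set (BT fractions,
or BT + WP), and that is how the degenerate-limit checks are formulated.

`run_course()` chains the whole workflow (rigid fusion → HU replacement →
both DIR modes → EQD2 → warp → sum → metrics for both scopes, plus the
addition baseline) into an `accumulation_report` with tibble outputs
(`tidy()`, `glance()`, `autoplot()`), and `cohort_summary()` aggregates
mean ± SD and 95% CIs over seeds. No hypothesis testing is performed.

## Numerical choices

* Trilinear interpolation with half-voxel edge extension; out-of-support
  fills are −1000 HU (CT), 0 Gy (dose), 0 (masks).
* Masks warp by trilinear interpolation of the 0/1 volume thresholded at
  0.5, so identity fields reproduce masks exactly; boundary ties after
  warping are resolved deterministically (uterus > rectum > bladder,
  clipped to the body) to preserve disjointness.
* Both empty masks in a Dice computation raise an error rather than
  returning 0/0.
* `d_cc` requests larger than the organ volume, empty organs/HR-CTV, grids
  that do not overlap, and non-invertible generative fields are all
  rejected with informative errors.
* All generators and both registration stages are deterministic for a fixed
  seed; repeated runs are byte-identical.

## Problem sizes

The package's own test suite exercises the full workflow on a 48 × 48 × 32
voxel phantom at 5 mm — the same world-space anatomy, deformation
amplitudes and noise as the default case, chosen so the whole suite stays
fast while preserving the registration behaviour (DSC levels, method
ordering and TRE relationships were verified to carry over). The
reproduction script (`scripts/acceptance.R`) runs the registration study at
the full default 96 × 96 × 64 / 2.5 mm resolution over five seeded cases.

## Known limitations

* The DIR surrogate shares only its *objective family* with commercial
  hybrid algorithms; absolute DSC values on phantoms (clean contrast,
  smooth ground-truth fields) are higher than clinical values.
* The inverse-square BT model ignores source anisotropy and scatter; EBRT
  boxes ignore tissue heterogeneity and beam modelling.
* Whole-organ contours are used for D$_x$ cm³ (no organ-wall extraction).
* One EBRT frame serves both WP and CS plans, as in the clinical workflow
  this emulates.
* No inverse-consistency constraint: fields are estimated one-way
  (frame → reference) only.
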