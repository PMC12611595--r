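---
title: "Dose-ring planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-ring planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic data can and cannot show, and the choices made where the design
was genuinely open. It states no empirical numbers beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The planning problem

Inverse planning for VMAT/IMRT turns a desired dose distribution into
machine parameters by minimizing weighted cost functions inside a
treatment planning system (TPS). Deep-learning dose prediction produces a
good 3D target distribution, but a predicted voxel grid is not something a
commercial TPS can optimize against directly. The pipeline implemented
here bridges that gap geometrically: the predicted distribution is
discretized into *ISO regions* (for each integer level \(k = 1..n\) Gy,
the region where dose strictly exceeds \(k\); coded 255/0) and *dose
rings* \(\mathrm{Ring}_k = \mathrm{ISO}_k \setminus \mathrm{ISO}_{k+1}\),
the voxels in the \((k, k+1]\) Gy band, with \(\mathrm{Ring}_n =
\mathrm{ISO}_n\). Rings become ROIs in an RTSTRUCT file, and a *fixed*
constraint template attaches a cost function to each ring: the plan
optimizer is thereby told, spatially, where each dose band belongs. The
same template serves every patient; nothing is tuned per case.

Two dialect templates are generated. The Monaco-style VMAT template uses a
target penalty on the prescription ring, an overdose-DVH chain (weight
0.01, reference dose \((k+1)\cdot100\) cGy, isoconstraint 0.01 %) on
Rings \(n-1\) down to 25, and a Body maximum dose; the SIB variant adds
underdose-DVH and maximum-dose functions for the 50 Gy boost ring and the
45 Gy base ring. The Pinnacle-style IMRT template constrains the
prescription ring with minimum/maximum/uniform-dose and min-DVH functions
and adds maximum-dose costs on ring∩organ intersections at 30, 33, 36 and
39 Gy. Constraints below Ring 25 are omitted: constraining every
low-dose ring slows optimization without improving plans. Ring
structures below 25 can still be *exported* (`export_all_rings = TRUE`);
only the constraints stop at 25.

Two readings of the ring construction conflict in the source material: the
subtraction order ("the \((n-1)\)th from the \(n\)th") is set-theoretically
inverted relative to the stated dose ranges ("1–2 Gy, 2–3 Gy, …"). The
implementation follows the ranges, which are unambiguous: \(\mathrm{Ring}_k
= \mathrm{ISO}_k \setminus \mathrm{ISO}_{k+1}\). Because "exceeded" is read
strictly, ring \(k\) covers the half-open band \((k, k+1]\); the band
semantics are asserted voxel-exactly in the tests.

## The synthetic cohort

No patient data ships with (or is needed by) the package; a phantom
generator stands in for the clinical cohorts. Its defaults are the study
conditions: a 128×128×64 grid at 3 mm; PTV45 volume goals of 1098 cm³
(VMAT) and 1447 cm³ (IMRT) and a PTV50 goal of 116 cm³, matching the
cohort averages; organs at risk (bladder anterior, rectum posterior,
small intestine superior, femoral heads lateral) as jittered
ellipsoids/tubes. OAR volumes are *plausible* pelvic defaults (≈250, 90,
500, 50 cm³) — the cohort publishes no OAR statistics, so these are not
calibrated quantities, and no test asserts them. Targets are built as
soft-min unions of ellipsoids whose semi-axes are rescaled (up to three
calibration passes of \((V_\mathrm{goal}/V)^{1/3}\)) until the voxelized
volume is within 2 % of the goal; the ±15 % acceptance band on achieved
volumes is then comfortable. HU values are class constants (soft tissue
≈ 40, bone ≈ 700, air −1000) with mild Gaussian texture — enough to
exercise CT normalization, with no beam-hardening realism.

The reference dose is a *distance-transform logistic*, not a beam model:
\(D(x) = 45\,\sigma\!\left(-d(x)/\sigma_p\right)\) with \(d\) the signed
Euclidean distance to the PTV45 surface (negative inside) and
\(\sigma_p = 8\) mm a penumbra width chosen to mimic clinical falloff; SIB
cases add \(5\,\sigma(-d_{50}/\sigma_p)\) toward 50 Gy inside PTV50. Dose
inside OAR∖PTV is reduced by a sparing depth (default 15 %) with smooth
blending, the result is capped at 1.10× the highest prescription, and the
grid is renormalized so each target meets the 95 % coverage rule. This
yields clinically shaped DVHs and the steep 45→50 Gy boost gradient that
drives the dice-similarity dip discussed below — but it is rotationally
smooth and noise-free, so passing tests say nothing about modulation
artifacts, scatter, or heterogeneity corrections in real plans.

One interaction is worth spelling out. A logistic centered on the target
surface puts boundary voxels near half the prescription, so renormalizing
to the 95 % coverage rule scales the grid well above 1 and the interior
saturates at the cap. The raw falloff model (for which the dose 3
penumbra-widths outside the target is below 5 % of the prescription) is
therefore exposed separately via `renormalize = FALSE`; the coverage and
cap guarantees are properties of the renormalized default, the falloff
bound a property of the raw model, and the tests assert each on the
object it belongs to.

## Preprocessing

CT volumes are windowed at width 600 / level 40 — clamp to
\([-260, 340]\) HU, then map linearly to \([0,1]\) — after an outer clamp
to \([-1000, 1000]\) HU that the window makes inert by default (the outer
interval is kept in the configuration because the windowing and the
clamp are stated separately in the source; the window dominates). All
volumes are resampled to 3 mm isotropic voxels: CT and dose trilinearly,
masks by nearest neighbour (masks must stay binary). Windowing is applied
before any augmentation; mirroring (the only augmentation offered) is a
left–right flip, which commutes with windowing anyway. Dose is
normalized by a modality maximum — 55 Gy for VMAT, 50 Gy for IMRT — so
network inputs and outputs live in \([0,1]\).

Plan renormalization scales the whole grid by \(\mathrm{Rx}/D_{95\%}\)
when coverage falls short, so that coverage meets the threshold *exactly*
rather than merely "at least" — deterministic, and the common clinical
normalization. \(D_q\) uses the linear-interpolation quantile of the
sorted in-mask doses (shared with the metrics module); because an
interpolated quantile can leave the voxel-counted coverage a hair under
the threshold, the implementation falls back to the exact order statistic
in that corner case, making the ≥ 95 % guarantee voxel-true. The
operation is idempotent and scale-equivariant, both asserted in tests.

## The dose-prediction network

The model is a 3D residual U-net with prediction fusion. Encoder: a 3×3×3
stem, then per level a strided 2×2×2 convolution and a residual block
(two 3×3×3 convolutions with instance normalization, identity skip,
PReLU). Decoder: transposed 2×2×2 convolutions, additive encoder skips,
residual blocks on the interior levels. With deep supervision on
(default), every decoder level emits a one-channel prediction through a
1×1×1 convolution; each lower-level prediction is upsampled ×2 (nearest)
and *added* to the next level's prediction, so the full-resolution output
fuses all scales. The output is linear, clamped at zero. All layers and
their gradients are hand-derived over im2col/GEMM kernels (Rcpp +
Armadillo); the backward pass is verified against central finite
differences in the test suite, which is the strongest correctness
statement a from-scratch implementation can make.

The composite loss is \(w_1\,\mathrm{MSE} + w_2\,\mathrm{MAE} +
w_3\,\mathrm{Rank}\) with unit weights. The rank term is a documented
interpretation — the cited construction is not spelled out in the source
— implemented as the simplest loss enforcing "predicted voxel ordering
matches the truth": sample \(P = 1024\) voxel pairs per step (seeded),
keep pairs with \(t_i > t_j\), and average the hinge
\(\max(0, m - (p_i - p_j))\) with margin \(m = 0\). It is zero exactly
when the sampled ordering is respected, and its gradient only reorders,
never rescales.

Clinical-scale training (hundreds of cases at full resolution on GPU) is
out of scope; the defaults are desk-scale. The fixture experiment the
acceptance suite runs — chosen once, as the package's toy problem — is a
32³ phantom at 9 mm spacing (same anatomy, coarser lattice, divisible by
the network's downsampling factor), 200 full-volume Adam steps at
learning rate 2×10⁻³ (an ordinary Adam rate for single-case overfitting;
the 10⁻⁴ default mirrors the clinical setting and is kept for multi-case
training), network depth 3 / width 8. The tests assert the 10-step
smoothed loss falls below 0.25× its initial value and that the
reconstructed dose is within 2 Gy mean absolute error inside the Body —
a parameter-recovery-style check that the architecture, loss and
optimizer actually fit the dose field they were built for.

## Evaluation metrics

DVHs are cumulative survival curves of the in-mask dose at 0.05 Gy
resolution; \(V_x\) counts voxels at or above \(x\); volumes are voxel
count × voxel volume (partial-volume effects ignored — a documented
limitation of every voxel pipeline). The exact conformity and
homogeneity formulas used clinically live in supplementary material that
is not public, so the package uses explicit, configurable stand-ins and
labels them as such: Paddick \(CI = TV_{PIV}^2/(TV\cdot PIV)\) and
\(HI = D_5/D_{95}\) (switchable to \(D_2/D_{98}\)); both are consistent
with the value ranges printed for the clinical cohorts (CI ≈ 0.81–0.93,
HI ≈ 1.03–1.08), which is a plausibility check, not a validation.

Dice similarity per isodose level compares \(\{D_A \ge L\}\) with
\(\{D_B \ge L\}\) for levels \(L\) from 10 % to 110 % of prescription.
Isodose masks here use inclusive ≥ (rings use strict >); the two differ
only on exact-tie voxels. When both regions are empty the DSC is defined
as 1 — at levels above every dose present, two distributions that agree
nowhere still agree about *emptiness*. The known sensitivity of DSC to
boundary shifts in steep-gradient regions is reproduced qualitatively: a
SIB phantom whose 50 Gy boost is deliberately mis-registered shows a dip
in the 90–100 % band with recovery above it. The test asserts the shape
(dip exists, recovery follows), never a value — the dip depth depends on
the phantom's gradient, not on anything the clinical study measured.

## Gamma analysis

The gamma module compares two *computed* grids; physical delivery
verification with a diode array is a measurement and out of desk scope.
The index is the standard Low construction: for each reference voxel at
or above the low-dose threshold (default 10 % of the reference maximum),
\(\gamma = \min_r \sqrt{\|r\|^2/\mathrm{DTA}^2 + \Delta D(r)^2 /
\Delta D_c^2}\) over a search ball (radius 3×DTA, step DTA/10, trilinear
interpolation of the evaluated grid), with \(\Delta D_c\) either global
(percent of the reference maximum — the common clinical default, used
here) or local. Neither the normalization nor the threshold is stated in
the source for the clinical QA, so the defaults are documented as
conventions, never asserted as the study's settings. Offsets are
processed in order of increasing distance and a voxel leaves the search
once the spatial term alone exceeds its current minimum — an exact
optimization, verified against an exhaustive-search oracle. Positions
outside the evaluated grid's extent are skipped rather than extrapolated.
The convention is reference-centric and deliberately asymmetric.

## Numerical and format choices

* **Coordinates**: DICOM patient (LPS) frame, 0-based voxel indices,
  voxel-center sampling, identity orientation only; oblique grids are
  rejected at read time.
* **Rasterization**: a voxel belongs to an ROI iff its center is inside
  the contour by the even-odd rule. Contours are extracted as exact
  voxel-edge polygons (vertices on voxel corners), so write→read
  round-trips masks voxel-identically and holes fall out naturally as
  separate loops.
* **RTDOSE storage**: 32-bit pixels scaled by
  \(\max(D)/(2^{31}-1)\), so a 55 Gy plan quantizes at
  \(55/2^{31}\) Gy; round-trip error is bounded by one quantum.
* **ISO-region export geometry**: ISO regions can be built on either the
  native or the 3 mm resampled grid; the pipeline uses the grid the dose
  lives on after preprocessing (the resampled one), since that is the
  grid the prediction is made on.
* **Determinism**: every stochastic component (phantom jitter, weight
  init, rank-pair sampling, perturbation noise, DICOM UIDs) derives from
  an explicit seed; the pipeline manifest records content hashes of all
  artifacts, and equal seeds reproduce equal hashes.
* **Desk-scale problem sizes**: the pipeline demo runs a 64×64×32 grid at
  6 mm; the training fixture a 32³ grid at 9 mm; gamma in the pipeline
  uses a 1 mm search step. These sizes are the package's choice of toy
  scale and are stated here so results are read at that scale.

## Known limitations

The phantom's dose model has no beam physics, so absolute OAR dosimetry,
delivery QA passing rates and planning-time comparisons from the clinical
study are out of reach by design. The DICOM layer is minimal: explicit VR
little endian only, axis-aligned grids, no RTPLAN. The network is
desk-scale; nothing here claims the clinical model's accuracy. CI/HI are
stand-in definitions. Template *content* is fixed and tested
field-for-field; the penalty algebra behind `evaluate_objective()` is the
package's own quadratic-hinge construction, isolated behind the
constraint abstraction precisely because the commercial cost formulas are
proprietary.
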