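# doserings

Automatic radiotherapy planning for pelvic (gynecological) cancer built on
two ideas: predict a patient's 3D dose distribution with a residual U-net,
then *discretize* that prediction into dose rings — the 1 Gy shells between
successive integer-gray isodose regions — and hand the rings, with a fixed
constraint-function template, to a commercial treatment planning system
(TPS) as optimization structures. The rings carry the spatial information a
plain DVH objective lacks, and the template is identical for every patient,
so the same recipe drives both Monaco-style VMAT and Pinnacle-style IMRT
optimization.

This package implements the full desk-scale pipeline in R, with no patient
data and no commercial TPS:

* **Synthetic pelvic phantoms** — CT-like volume, Body/PTV/OAR masks with
  cohort-scale target volumes (PTV45 ≈ 1098 cm³ VMAT / 1447 cm³ IMRT,
  PTV50 ≈ 116 cm³ for simultaneous-integrated-boost cases), and a
  distance-transform reference dose renormalized to the 95 % coverage rule.
* **DICOM-RT I/O** — minimal CT-series / RTDOSE / RTSTRUCT reader and
  writer (explicit VR little endian, axis-aligned grids), with exact
  voxel-edge contour extraction so masks round-trip voxel-identically.
* **Preprocessing** — CT windowing (width 600 / level 40 → `[-260, 340]`
  mapped to `[0, 1]`), 3 mm isotropic resampling, dose normalization
  (55 Gy VMAT / 50 Gy IMRT), plan renormalization to 95 % coverage.
* **Dose prediction** — a 3D fusion residual U-net (strided 2×2×2
  convolutions, transposed-convolution decoder, instance normalization,
  PReLU, deep supervision with upsample-and-add prediction fusion) with a
  composite MSE + MAE + pairwise-rank loss, trained with Adam. The layers
  and backward passes are implemented in this package over Rcpp
  im2col/GEMM kernels and run on CPU.
* **Rings** — ISO regions (voxel coded 255 when dose strictly exceeds the
  k Gy level), ring differences `Ring k = ISO(k) \ ISO(k+1)` covering the
  `(k, k+1]` Gy band, ring∩organ intersections, RTSTRUCT export with
  low-dose rings below Ring 25 excluded.
* **Constraint templates** — the Monaco single-target, Monaco SIB and
  Pinnacle IMRT dose-ring constraint tables (cost type, weight, reference
  dose in cGy, isoconstraint), serialized to a tabular text format, plus a
  quadratic-hinge objective evaluator.
* **Evaluation** — cumulative DVH, V_x / D_q / D_mean, Paddick conformity
  index CI = TV_PIV² / (TV·PIV), homogeneity index HI = D5/D95, dice
  similarity per isodose level, and Low-type gamma analysis at 3 %/3 mm
  and 3 %/2 mm.

## Worked example

```r
library(doserings)

spec <- phantom_spec(seed = 7)                  # 128x128x64 at 3 mm, VMAT
case <- generate_case(spec)
dose <- generate_reference_dose(case)
mask_volume_cm3(case$structures[["PTV45"]])
#> [1] 1097.01
v_at(dose, case$structures[["PTV45"]], 45)      # % of PTV45 at >= 45 Gy
#> [1] 95.00615

rings <- make_rings(make_iso_regions(dose, n = 45))
rings
#> <ring_set> Ring 1..Ring 45 (45 non-empty) on 128x128x64 @ 3x3x3 mm

tpl <- build_template("monaco_vmat_single", n = 45, min_level = 25)
template_functions(tpl, "Ring 43")
#>   structure         cost weight ref_cgy  iso
#> 3   Ring 43 overdose_dvh   0.01    4400 0.01
```

The PTV45 volume lands on the cohort-average goal (1098 cm³ within the
calibration tolerance); the reference dose meets the 95 % coverage rule by
construction; the Ring 43 row reproduces the printed template content: an
overdose-DVH cost of weight 0.01 whose reference dose is `(k+1)·100 =
4400` cGy, i.e. the upper edge of the ring's dose band.

An end-to-end run (phantom → preprocessing → prediction surrogate → rings →
template → objective → metrics → gamma) with a JSON manifest:

```r
run_pipeline("out/demo", seed = 7)
```

or from a shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/autoplan.R pipeline --out out/demo --seed 7
Rscript inst/cli/autoplan.R template --dialect pinnacle_imrt --out imrt.tsv
```

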