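# pediplan

CT-value-based automatic pedicle screw trajectory planning in R.

## The problem

Pedicle screw fixation in osteoporotic vertebrae fails when the screw
sits in low-density bone: pull-out strength tracks the bone mineral
density (BMD) of the corridor the thread occupies, and BMD is linearly
related to the CT attenuation value (Hounsfield units, HU). Instead of
the conventional geometric plan — through the midpoint of the narrowest
pedicle section, parallel to the endplate — a planner can therefore
search for the corridor with the highest mean CT value that still
respects the anatomy.

`pediplan` implements that planner for surgeons, biomechanics
researchers and navigation-software developers. Given a CT volume, a
compartment label volume and a screw size (D × L, e.g. 6 mm × 30 mm),
it solves

```
max over (entry e, direction u):   mean HU of the cylinder C(e, u; L, D)
subject to:  C contained in bone            (no pedicle/cortex breach)
             C intersects the narrowest-pedicle-section ROI
             screw tip clear of the anterior vertebral cortex
```

with a deterministic grid + pattern search. Alongside the planner it
provides:

* the **manual-planning baseline** (narrowest-section midpoint,
  endplate-parallel, on the pedicle axis),
* **trajectory position measurements** on axial/sagittal views
  (distances d, d′; angles θ, θ′; abduction = 90° − θ; craniocaudal
  inclination = θ′ − 90°) plus placement error (d₁ − d, θ₁ − θ),
* the **T′ osteoporosis score**, T′ = (measured CT value − reference
  mean)/reference SD, osteoporotic at T′ ≤ −2.5,
* a **synthetic vertebra phantom** with ground-truth geometry and a
  linear decalcification model (an in vitro osteoporosis model in
  silico), used for validation,
* NIfTI I/O, trajectory JSON, guide-plate coordinate export and a thin
  command-line front end (`inst/cli/pediplan`).

## Worked example

Plan both trajectories on a synthetic vertebra carrying a planted dense
corridor (+500 HU, radius 2.5 mm, offset 2 mm from the pedicle axis):

```r
library(pediplan)

ax <- generate_phantom(phantom_spec(seed = 7))$truth$pedicle_axes$left
ph <- generate_phantom(phantom_spec(
  seed = 7,
  corridor = list(point = ax$point + c(0, 0, 2), direction = ax$direction,
                  radius = 2.5, hu_boost = 500)))
dm <- distance_map(ph$labels)
frame <- frame_from_truth(ph$truth, "left")

manual <- plan_manual(ph$ct, ph$labels, frame, "left", dmap = dm)
auto <- plan_auto(ph$ct, ph$labels, frame, "left",
                  settings = search_settings(entry_grid_step = 1.5,
                                             cone_half_angle = 10,
                                             angular_step = 2.5),
                  dmap = dm)
```

```
> manual
manual plan: mean corridor CT value 3031.7 HU (1 candidate evaluations)
trajectory: 6.0 x 30.0 mm screw
  entry (-14.76, -36.25, 0.00) mm -> tip (-9.06, -6.80, 0.00) mm
feasible: TRUE
  contained: TRUE (margin 0.20 mm)
  passes narrowest pedicle section: TRUE
  anterior margin safe: TRUE (clearance 3.05 mm)

> auto
auto plan: mean corridor CT value 3213.8 HU (1265 candidate evaluations)
trajectory: 6.0 x 30.0 mm screw
  entry (-14.76, -36.25, 1.50) mm -> tip (-9.22, -6.77, 1.50) mm
feasible: TRUE
  contained: TRUE (margin 0.00 mm)
  passes narrowest pedicle section: TRUE
  anterior margin safe: TRUE (clearance 2.49 mm)

> measure_trajectory(auto$trajectory, frame)
axial:    d = 14.76 mm, theta = 79.36 deg (abduction 10.64 deg)
sagittal: d' = 16.50 mm, theta' = 90.00 deg (craniocaudal 0.00 deg)

> percent_difference(auto$mean_hu, manual$mean_hu)
[1] 6.009298
```

The automatic plan shifts 1.5 mm toward the planted corridor and gains
6.0% mean corridor HU over the manual baseline while staying fully
contained (margin 0.00 mm — the objective rewards corridors hugging the
cortex; boundary contact counts as contained). A containment margin is
the minimal clearance between the corridor surface and the bone
exterior; the anterior clearance is the same quantity at the screw tip.

Densitometry works directly on group statistics:

```
> t_prime(2688.80, ref_mean = 2767.87, ref_sd = 26.15)
T' = -3.02 (CT 2688.80 HU vs reference 2767.87 +/- 26.15 HU) -- osteoporotic
```

The command line mirrors the R API:

```sh
Rscript inst/cli/pediplan phantom --out ct.nii.gz --labels labels.nii.gz \
    --truth truth.json --seed 4
Rscript inst/cli/pediplan plan-auto --ct ct.nii.gz --labels labels.nii.gz \
    --truth truth.json --side left --out traj.json --report plan.json
Rscript inst/cli/pediplan export-guide --traj traj.json --out guide_points.csv
```

`guide_points.csv` holds the entry and stop (tip) world coordinates —
the inputs a patient-specific 3D-printed drill guide is designed from.

## Package layout

| Path | Contents |
| --- | --- |
| `R/volume-model.R` | CT/label containers, NIfTI I/O, affine maps, trilinear sampling, distance maps |
| `R/phantom.R` | synthetic vertebra generator, decalcification model and calibration |
| `R/geometry.R` | trajectories, frames, corridor quadrature, measurements, guide export |
| `R/constraints.R` | containment / ROI-passage / anterior-margin checks |
| `R/planners.R` | manual baseline, automatic planner, enumeration oracle, screw sizing |
| `R/densitometry.R` | T′ score, group transforms, percent comparisons, study report |
| `src/` | exact anisotropic Euclidean distance transform, fast volume sampling (Rcpp) |
| `vignettes/trajectory-planning.Rmd` | models, conventions, numerical choices, limitations |
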