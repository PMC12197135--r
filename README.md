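# pneumoshift

Quantifies how retroperitoneal vascular and organ landmarks move on CT
when the abdomen is insufflated (intra-abdominal pressures of 0, 5, 15,
25 mmHg) and when the patient is repositioned (supine, 45° lateral
decubitus either side, ±15° Trendelenburg) — the displacement budget that
limits rigid image-guided navigation in laparoscopic and robotic
retroperitoneal surgery. It is written for analysts working with fiducial
landmark coordinates exported from CT workstations (3D Slicer markups
FCSV, or a plain long-format CSV).

## The statistic

Six bony landmarks (`R1`–`R6`: both ASIS, upper symphysis edge, S1, both
XII rib tips) form a rigid reference matrix; seven targets (`P1`–`P7`:
aortic bifurcation, renal arteries, kidney hila, SMA, celiac artery) are
tracked. For target *t* between scans *b* and *c*, with *dᵢ* the
intra-scan Euclidean distance from reference *i* to the target:

> Δ̄ₜ = (1/n) Σᵢ | dᵢ(b) − dᵢ(c) | ,  reported as mean (SD) over n = 6 references

Only within-scan distances enter, so the statistic needs no inter-scan
registration and is exactly invariant to rigid body motion. By the
reverse triangle inequality it is a *lower bound* on the true target
displacement — the package ships a ground-truth evaluator (least-squares
rigid/Kabsch registration on the bony frame, `true_displacement()`) and a
synthetic 20-scan study generator with exact ground truth to measure that
attenuation.

## Worked example

References on an octahedron of radius 10 mm around a target that truly
moves 1 mm:

```r
library(pneumoshift)
refs <- rbind(R1 = c(10,0,0), R2 = c(-10,0,0), R3 = c(0,10,0),
              R4 = c(0,-10,0), R5 = c(0,0,10), R6 = c(0,0,-10))
b <- scan_landmark_set(scan_condition("supine", 0),  rbind(refs, P1 = c(0,0,0)))
c <- scan_landmark_set(scan_condition("supine", 15), rbind(refs, P1 = c(1,0,0)))
displacement(b, c, "P1")$mean_abs_diff_mm
#> [1] 0.3665837
true_displacement(b, c, "P1")
#> [1] 1
```

The surrogate reports 0.37 mm for a true 1 mm shift: two references lie
along the motion and see the full 1 mm; the four perpendicular ones see
√101 − 10 ≈ 0.05 mm each.

The full pipeline, on a simulated study (`analysis/01` … `05` run these
steps and write `results/`):

```r
bundle <- run_pipeline(run_config(simulate = TRUE, out_dir = "results"))
nrow(bundle$pressure_table)   # 7 targets x 3 pressures x 5 positions
#> [1] 105
nrow(bundle$position_table)   # 7 targets x 4 positions x 4 pressures
#> [1] 112
```

With the default simulator settings the pressure-effect cells average
2.2 mm and the position-effect cells 2.6 mm (repositioning moves targets
more than insufflation alone), and three simulated re-placements of every
fiducial give a pooled repeatability of 2.8 mm — the mean pairwise
placement distance implied by the 1.24 mm-per-axis placement noise
(4σ/√π). Cell renderings follow the reporting convention `"mean (sd)"`
at 0.1 mm.

## Layout

- `R/` — the package: landmark model and I/O (`read_fcsv`,
  `read_long_csv`), displacement statistics and comparison tables,
  rigid-registration ground truth, the synthetic study generator, and the
  `run_pipeline()` orchestrator.
- `analysis/01_simulate_study.R` … `05_surrogate_vs_truth.R` — numbered
  drivers that simulate a study, measure distances, build both tables,
  estimate repeatability, and validate the surrogate against ground
  truth, writing tables under `results/`.
- `vignettes/displacement-methods.Rmd` — the model, conventions,
  simulator assumptions and limitations.

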