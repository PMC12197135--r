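---
title: "Measuring retroperitoneal landmark displacement without registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retroperitoneal landmark displacement without registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image-guided laparoscopic and robotic surgery overlays preoperative CT
anatomy on the live scene. Two intraoperative factors move retroperitoneal
structures away from their preoperative positions: CO2 insufflation
(intra-abdominal pressure, IAP, typically 10--15 mmHg, here studied at
0/5/15/25 mmHg) and patient positioning (supine, 45° lateral decubitus
either side, ±15° Trendelenburg tilt). This package quantifies that
displacement from fiducial landmark coordinates placed on CT scans across
the full 5 × 4 factorial of conditions — 20 scans in all — and validates
the statistic used to do so.

## The displacement surrogate

Six bony landmarks (`R1`--`R6`: both anterior superior iliac spines, the
upper symphysis edge, the first sacral vertebra, and both twelfth rib
tips) form a rigid reference matrix. Seven vascular/organ targets
(`P1`--`P7`: aortic bifurcation, renal arteries, kidney hila, superior
mesenteric and celiac arteries) are the structures of interest. For a
target $t$ compared between a baseline scan $b$ and a comparison scan
$c$, with $d_i(\cdot)$ the Euclidean distance from reference $i$ to the
target within one scan, the surrogate is

$$\bar{\Delta}_t = \frac{1}{n}\sum_{i=1}^{n}\bigl|\,d_i(b) - d_i(c)\,\bigr|,$$

reported with its standard deviation over the $n = 6$ references. Because
only intra-scan distances enter, no registration between scans is needed
and the statistic is exactly invariant under rigid motion of either scan
— repositioning the body cannot create spurious displacement.

The price is systematic under-reporting: by the reverse triangle
inequality, $|d_i(b) - d_i(c)| \le \lVert t_b - t_c \rVert$ for every
reference when the references are noise-free in a common bony frame, so
$\bar{\Delta}_t$ is a lower bound on the true displacement. The package's
worked example makes this concrete: with references on an octahedron of
radius 10 mm and a central target shifted by 1 mm, the surrogate reports
0.3666 mm. `surrogate_vs_truth()` quantifies this attenuation on
simulated studies, where `true_displacement()` — least-squares rigid
(Kabsch) registration on the bony references, then the target's residual
motion — provides the ground-truth counterpart. On the default simulated
geometry the noiseless median surrogate/truth ratio is computed by
`analysis/05_surrogate_vs_truth.R`.

Two conventions are configurable because the field reports both and the
choice is not otherwise forced:

* **SD denominator** — sample SD ($n-1$, default) or population SD;
  with six references the two differ by $\sqrt{5/6}$.
* **Missing-landmark policy** — `strict` (default) refuses scans whose
  reference matrix is incomplete, so SDs stay comparable across table
  cells; `permissive` computes over the common reference subset and
  records `n_references` per cell.

## Comparison tables

`pressure_effect_table()` compares, within each position, each non-zero
IAP against that position's 0 mmHg scan: 7 targets × 3 pressures × 5
positions = 105 cells. `position_effect_table()` compares, at each IAP,
each non-supine position against the supine scan at the same pressure:
7 × 4 × 4 = 112 cells. Cells whose comparison scan is absent are reported
missing (`NA`, rendered as an em dash), never zero; a comparison level
absent from the whole study is dropped and flagged. Internal math runs at
full double precision; `render_wide_table()` rounds to 0.1 mm only at the
reporting stage.

## Fiducial repeatability

Placing a virtual fiducial on a CT image is itself noisy. With replicate
placements of one scan, `repeatability()` summarises, per landmark, the
Euclidean distances between all unordered placement pairs (default), or
each placement's distance to the replicate centroid — both are offered
because "repositioning accuracy" admits either reading, and neither is
claimed to reproduce any previously printed value. Pooling is split into
bone references and anatomical targets. For isotropic Gaussian placement
error with SD $\sigma$ per axis, two placements differ by
$\sigma\sqrt{2}\,\chi_3$, so the mean pairwise distance has the closed
form $4\sigma/\sqrt{\pi} \approx 2.2568\,\sigma$ — the calibration used
by the simulator's default noise level.

## The synthetic study generator

No landmark coordinates from the original cadaveric experiment are
available, so every pipeline stage is exercised on a simulated torso
(`phantom_spec()`, `simulate_study()`) whose deformations carry exact
ground truth. The phantom places the six bony references at anatomically
plausible pelvis/rib-tip coordinates and the seven targets midline and
retro-aortic, in RAS millimetres (the native frame of the fiducial
files). The deformation model, `deformation_params()`, is deliberately
simple and makes no claim of biomechanical fidelity:

* **Insufflation** pushes each target anteriorly by
  $\alpha \, p \, e^{-\mathrm{depth}/\lambda}$ — linear in pressure,
  attenuated exponentially with depth from the anterior abdominal wall.
  Defaults $\alpha = 1$ mm/mmHg, $\lambda = 60$ mm, depths 105--135 mm
  put pressure-effect cells in the low-millimetre range, the magnitude
  regime reported for IAP effects on retroperitoneal targets. Bony
  references do not move.
* **Positioning** rotates the whole body rigidly (lateral decubitus
  about the cranio-caudal S axis, Trendelenburg tilts about the
  left-right R axis, signed per position), then lets soft tissue sag
  along gravity by `sag_compliance` times the chord length
  $2\sin(\theta/2)$ of the body-frame gravity-direction change. Default
  compliances of 4--9 mm per target put position-effect cells in the
  several-millimetre range, larger than pressure effects — the
  qualitative contrast the simulated study is meant to reproduce.
  References have zero compliance, so the bony constellation stays
  congruent with baseline.
* **Placement noise** is isotropic Gaussian, i.i.d. across landmarks and
  scans, applied after deformation — modelling operator fiducial
  placement, the dominant measurement-error source. The default
  $\sigma = 1.24$ mm makes the mean pairwise replicate distance
  $\approx 2.8$ mm, matching the observed repositioning accuracy of
  virtual fiducials.

Ground truth is the *noiseless* soft-tissue displacement of each target
in the bony frame, relative to the supine/0 mmHg baseline; the recorded
vectors agree with registration-based `true_displacement()` on noiseless
sets to 1e-9 mm (a bookkeeping invariant under test). What passing tests
on this simulator do **not** show: fidelity of the deformation family to
real cadaveric or living tissue (no finite-element mechanics, no surgical
retraction, no per-axis direction validation), or robustness to
non-Gaussian operator error.

## Numerical choices

* Canonical frame: RAS millimetres throughout; LPS fiducial files are
  converted on read (x, y negated), and the conversion is an involution.
* Rigid fits reject reflections (determinant forced +1) and refuse
  degenerate geometry (second singular value of the centred reference
  matrix below 1e-6 of the first, or fewer than 3 common references).
* Zero thresholds: surrogate/truth ratios are defined as 1 when both are
  below 1e-9 mm and flagged `NA` when only the truth is; rigid-invariance
  assertions use 1e-9 mm.
* Long-format CSV serialises coordinates at 17 significant digits so
  write-then-read round-trips are bit-exact.
* `R7` (distal sternum tip) and `SKIN_*` fiducials are recognised on
  input but excluded from analysis by default — the sternum moves with
  abdominal expansion and skin markers move with repositioning —
  overridable via the YAML alias/exclusion config.

## Problem sizes

The test suite and acceptance script run the full pipeline at the study's
own scale (20 scans, 13 landmarks) and use 50 replicate studies for
stochastic checks, 1000 random configurations for kernel oracles, and
12,000 simulated placements for the repeatability closed form — sizes
chosen so each check's Monte-Carlo error is far below its assertion
tolerance while the whole suite stays interactive.

## Known limitations

The surrogate's attenuation factor depends on the reference--target
geometry, so its values are comparable across conditions within one
subject but are not absolute displacement estimates; the simulator's
deformation family is a three-parameter caricature; and repeatability is
estimated from three replicates per landmark, as in the underlying
acquisition protocol, so per-landmark SDs are themselves noisy.
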