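---
title: "Measuring macular curvature from radial OCT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring macular curvature from radial OCT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcindex)
```

## The measurement model

Posterior staphyloma is an outpouching of the posterior eye wall whose local
radius of curvature is smaller than that of the surrounding wall. The
retinal pigment epithelium (RPE) segmentation line on an OCT B-scan traces
the posterior wall contour, so the steepest curvature along that line is a
natural screening quantity.

The measurement is a deliberately simple, raw three-point construction.
Working in physical coordinates — lateral position `x = col * px_h`, depth
`z = row * px_v`, both in mm — an arc is placed at every column `a` of the
region of interest through the three line points at columns `a - k`, `a`,
`a + k`, where `k = round(1.4 mm / px_h)` (100 columns at the 0.014 mm/px
pitch of a 9-mm, 643-column scan). The recorded value is the circumradius
of those three points. The per-scan minimum is `r`; the mean of `r` over
the eye's radial scan set (nominally 12 scans, evenly spaced over 180
degrees through the fovea) is `R`; and the macular curvature index is

$$\mathrm{MC} = \frac{337.5}{R}.$$

337.5 is the keratometric constant that converts a corneal radius in mm to
diopters; reusing it makes MC directly comparable with keratometry — MC 40
corresponds to the curvature of a 40 D cornea, both at radius
337.5/40 = 8.4375 mm (8.44 rounded). The constant is intentionally not
configurable: changing it would silently break comparability of MC values.

Classification against the reference uses, by default, the empirically
observed gray zone rather than a sharp cutoff: indices above 42.7 are
reported as staphyloma-consistent, below 37.5 as consistent with no
staphyloma, and values between as indeterminate. A strict single-cutoff
mode (`use_band = FALSE`, MC > 40) is available.

### Assumptions

* The RPE line is a single-valued function of the lateral coordinate (a
  "graph"); multi-valued pathology such as a retinal detachment fold is out
  of scope.
* The arc endpoint offset is measured in columns (lateral distance), not
  arc length: "pixels apart" on a raster line means columns.
* Scans of one eye share the lateral pitch and are centered on the fovea;
  the tool checks the former and takes the latter on trust.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `px_h_mm` | 0.014 | mm/px | lateral pitch; 643 columns × 0.014 = 9.0 mm scan |
| `px_v` | from metadata | mm/px | axial pitch of the stored raster — required, never guessed |
| `chord_offset_mm` | 1.4 | mm | lateral offset from the evaluated column to each arc endpoint |
| `roi_margin_cols` | 100 | columns | excluded at each lateral edge |
| `expected_scans` | 12 | — | nominal radial protocol size |
| `mc_reference` | 40 | — | single-cutoff reference |
| `indeterminate_band` | [37.5, 42.7] | — | empirical gray zone |

Two readings of the chord construction are possible: endpoints 1.4 mm
*from the evaluated column* (full chord 2.8 mm, the reading adopted as the
default, following the per-column "100 pixels apart" construction at
0.014 mm/px), or endpoints 1.4 mm *from each other*. `chord_offset_mm` is
an explicit knob so the alternative (0.7) can be run as a sensitivity
analysis; all shipped defaults use 1.4.

Whether the 100-column edge margin is applied before or after any display
de-stretch is immaterial here because the margin is lateral and the stretch
is vertical; the effective margin is additionally never allowed to fall
below `chord_offset_cols`, so both arc endpoints always exist.

## Numerical choices

* **Collinearity.** A three-point arc with twice-the-triangle-area below
  1e-12 mm² returns the infinite-radius sentinel (`Inf`) instead of a huge
  unstable quotient. Sentinel columns are excluded from the per-scan
  minimum; a scan whose whole ROI is collinear (a genuinely flat wall) is
  flagged and excluded from `R`, with a warning in the result rather than a
  hard failure.
* **Ties.** The minimum's column is the first occurrence, for determinism.
* **Gaps.** Vessel shadows and dropouts leave missing columns. Up to 20%
  missing is filled by linear interpolation (nearest-value extension at the
  edges); beyond 20% the scan is rejected — interpolating more would let
  fabricated geometry dominate `r`.
* **Aspect.** Review software commonly displays B-scans elongated 2× in
  depth. All geometry here is computed in mm from the stored raster's true
  pitches, so the elongation is absorbed by the conversion: doubling stored
  row positions while halving the pitch is bit-exactly the same line
  (multiplications by 2 and 0.5 are exact in floating point). For rasters
  saved in duplicated-row display form, `correct_aspect()` decimates the
  duplicate rows — the lossless inverse of that presentation — which makes
  stretched and unstretched inputs agree to the bit.
* **Fewer than 12 usable scans** aggregate with a recorded warning instead
  of a refusal: dropped scans are a fact of clinical acquisition and the
  warning keeps the shortfall auditable.
* **Dialect precision.** Segmentation-line JSON round-trips depths
  bit-exactly (17 significant digits); the CSV dialect carries 9 decimals.

## The RPE detector

Device exports are the intended primary input; the built-in detector is a
validated stand-in for B-scans that arrive as bare images. Per column the
intensity trace is smoothed by a short axial moving average
(`axial_smooth_rows`, default ±4 rows), contiguous runs of at least two
rows above `min_contrast` (default 0.2 on the normalized intensity scale)
are found, and the *deepest* run is taken — the RPE is the posterior-most
strongly hyperreflective band. Its depth is the centroid weighted by
intensity above threshold, which is exact for a symmetric band and gives
sub-pixel accuracy; a cross-column rolling median (±5 columns, window
shrunk symmetrically at the scan edges to avoid one-sided bias) removes
isolated glitches. Columns with no qualifying band become gaps; more than
20% of them is a detection failure naming the scan. On noiseless rendered
phantoms the detector reproduces the generating line to within half an
axial pixel at every column; at additive intensity noise of σ = 0.1 the
median depth error stays below one axial pixel.

## The phantom: what it emulates and what it does not

The synthetic eye is the inside view of a spherical posterior pole of
radius ρ (fovea deepest, wall depth normalized to `depth_offset_mm` at the
scan edges) plus an optional isotropic 3-D Gaussian outpouching of depth
amplitude `A` and width `σ`:

$$z(x) = z_0 + \sqrt{\rho^2 - x^2} - \sqrt{\rho^2 - (w/2)^2}
       + A\,e^{-(x - x_0)^2 / 2\sigma^2}.$$

A radial scan at angle θ through a bump centered `d` off-axis at azimuth φ
sees it at lateral position `d·cos(θ−φ)` with amplitude reduced by
`exp(−(d·sin(θ−φ))²/2σ²)` — the exact restriction of the 3-D bump to the
scan plane, so off-center phantoms exercise the 12-scan averaging
nontrivially. At a centered apex the curvature is exactly
`1/ρ + A/σ²`, giving a closed-form target radius; for `A = 0` every
three-point arc returns ρ identically, which pins the whole pipeline to
`MC = 337.5/ρ`.

Note the three-point radius over a finite 2.8-mm chord on a non-circular
curve is *biased above* the osculating radius at a narrow bump — a property
of the construction itself, not an implementation error. Validation
tolerances are therefore set against a brute-force three-point oracle
evaluated on the continuous phantom curve, never against the osculating
value.

Rendered B-scans place a Gaussian-profile bright band (thickness parameter
= 2 band-profile sigmas) on the line with additive Gaussian intensity
noise, seeded per scan angle so all output is a pure function of
(spec, seed). The phantom makes no attempt at OCT speckle statistics,
multiple retinal layers, shadowing artifacts, or curved A-scan geometry —
so passing phantom tests demonstrates correctness of the geometry and
detection machinery, not robustness to every clinical artifact. Device
segmentation failures on real staphylomas are the reason the
correction-overlay mechanism exists.

Default phantom conditions mirror the target protocol: 12 scans, 643
columns at 0.014 mm/px (9.0 mm), axial pitch 0.0026 mm/px (a typical
swept-source axial sampling; the display stretch factor defaults to 2).
Cohort-level test conditions use globes of ρ ∈ [9.5, 13] mm (no bump;
MC ≤ 35.5, below the gray zone by construction) and outpouchings of
A ∈ [0.3, 0.6] mm, σ ∈ [1.0, 1.5] mm (apex radii ≈ 2.5–4.5 mm, far inside
the staphyloma-consistent range) — sized like the anatomy they stand in
for, and deliberately not tuned to sit near the decision boundary, where
the finite-chord bias would make classification of a *phantom* ambiguous
even though the construction is behaving exactly as designed.

## A worked measurement

```{r example}
sp <- phantom_spec(rho_mm = 12, bump_A_mm = 0.35, bump_sigma_mm = 1.2,
                   eye_id = "vignette_eye")
phantom_apex_radius(sp)          # closed-form apex radius, mm

res <- process_eye(phantom_eye(sp))
res
res$per_scan[1:3, ]
```

The problem sizes used throughout the test suite match these defaults
(hundreds of columns, tens of eyes), which keeps the full validation run in
the tens of seconds.

## Known limitations

* The index summarizes the steepest *cross-sectional* curvature; it does
  not localize staphyloma subtype or model 3-D wall shape across scans.
* The chord-offset reading ambiguity (above) changes the absolute scale of
  `r` on strongly non-spherical walls; comparisons should fix
  `chord_offset_mm`.
* The gray-zone band is an empirical observation from one cohort, exposed
  as configuration rather than a claim of generality.
* No DICOM or proprietary OCT container ingestion; inputs are plain
  TIFF/PNG images or line exports.
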