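---
title: "Phantom QA metrics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom QA metrics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phantomqa` computes scanner quality-assurance metrics from magnitude images
of a homogeneous cylindrical phantom. This vignette explains the underlying
models, the assumptions each metric makes, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the conventions leave room.

## The measurement model

A magnitude MR image of a uniform phantom is modelled as the modulus of a
complex signal plus complex Gaussian noise with per-channel SD σ. Two
consequences drive the metric definitions:

- inside the phantom (signal ≫ σ) the voxel noise is approximately Gaussian
  with SD σ (Rician, high-SNR limit);
- in air, the magnitude is Rayleigh distributed with SD σ·√((4−π)/2) and
  mean σ·√(π/2).

The single-image SNR estimator divides the signal-ROI mean by the
*background* SD and multiplies by √((4−π)/2) to undo the Rayleigh
compression; it is exact in expectation only if the background is pure
noise. The subtraction estimator avoids that assumption by differencing two
repetitions — at the cost of sensitivity to inter-repetition instability,
which inflates SD₂. This is why the ratio SNR₁/SNR₂ is itself a diagnostic:
it should be ≈ 1, and the package flags (but never fails on) values outside
[0.9, 1.1]. QA metrics are monitoring instruments; turning them into hard
gates is a site policy decision, so the package reports and warns only.

## Automatic masking

Detection assumes a single bright, roughly circular object on a dark
background: Otsu threshold (256 bins; the threshold is taken at the upper
edge of the winning bin so values binned into the lower class never leak
into the mask), largest 8-connected component, hole filling, boundary-pixel
extraction, and an algebraic least-squares (Kåsa) circle fit. Boundary pixel
*centres* lie on average half a pixel inside the true edge, so 0.5 px is
added to the fitted radius; with this correction, simulated scenes at SNR 50
are recovered to < 0.5 px in centre and < 1 px in radius (enforced by the
test suite). Detection errors are raised, not guessed around: no component
covering ≥ 1% of the image means "phantom not found", and a foreground
touching all four borders is "not separable".

ROI geometry follows the conventional layout:

- the signal ROI is a circle of 80% of the phantom's diameter;
- the extreme-intensity ROIs are ~1 cm² circular kernels, slid over every
  position where the kernel fits entirely inside the signal ROI; ties are
  broken toward the smallest (row, col) so results are deterministic;
- four ~10 cm² background rectangles hug the image borders along the
  frequency- and phase-encode axes, centred on the phantom's centre lines,
  inset 2 px from the borders and kept disjoint from the phantom dilated by
  2 px. Their aspect is long:short ≈ 4:1 with the long side parallel to the
  hugged border — the printed area is what the convention fixes, not the
  shape, so the achieved areas are reported in the output;
- the temporal ROI is a 15×15-pixel square centred on the phantom centre
  rounded to the nearest pixel. The EPI analysis detects its own centre (on
  the temporal mean image, which is far less noisy than any single volume)
  rather than reusing the spin-echo centre, since the two acquisitions are
  masked independently.

Physical areas are converted to pixel counts through the pixel spacing and
rounded to the nearest realizable discrete shape; with anisotropic spacing
the circular kernels become elliptical in pixel units. The phase-encode axis
is explicit configuration (default `"row"`), never inferred from headers:
orientation metadata is notoriously inconsistent across vendors, while the
QA protocol fixes the PE direction by design.

## Temporal analysis

All temporal metrics operate on the central slice after discarding the first
two volumes (gradient/spin steady state), leaving 198 of the standard 200.
Per-pixel and ROI-averaged series are detrended with a second-order
polynomial fitted by least squares on a centred, rescaled time index — the
fitted values are mathematically identical to a naive polynomial regression,
the centring only improves conditioning (verified against `stats::lm` in the
tests). Sample SDs use n−1 throughout; the residual of a fit containing an
intercept has exactly zero mean, so the residual SD needs no re-centring.

The Weisskoff analysis estimates, for square ROIs of side N = 1…15, the SD
of the detrended ROI-mean series. Because detrending is a linear projection,
averaging pixel series and then detrending equals averaging per-pixel
residuals — the package uses the former, and the test suite checks the
equivalence against an explicit double-loop evaluation. Each N defines its
own ROI-mean series and is detrended separately. For even N a square cannot
be centred on a pixel; the ROI is anchored so the centre pixel sits at
offset ⌊N/2⌋, i.e. it extends one pixel further toward lower indices —
fixed, documented, deterministic. The RDC is evaluated at N = 15 (the
largest measured side length, configurable through `max_n`) and is *not*
clamped to [1, 15]: under near-ideal iid noise the estimate fluctuates
around 15 and can exceed it; clamping would hide exactly the instability of
the estimate the user should see, so out-of-range values are reported as
computed with a warning.

## The synthetic-data generator

`qa_scenario()` + `simulate_se()` / `simulate_epi()` generate the scenes the
test suite and the acceptance script analyse. The generator emulates:

- a uniform disk with a radial parabolic intensity dip (shading depth *d*,
  emulating receive-coil/B1 non-uniformity);
- genuinely Rician/Rayleigh magnitude statistics, by adding noise in the
  complex domain before taking magnitudes — required for the √((4−π)/2)
  correction to be exact in expectation;
- an N/2 ghost: a half-matrix circularly shifted replica of the scene along
  the PE axis, scaled by `ghost_fraction`;
- a multiplicative quadratic temporal trend `1 + b·u + c·u²` (u ∈ [0, 1]),
  so `b` *is* the peak-to-peak drift fraction when c = 0;
- a spatially coherent instability: a Gaussian-smoothed unit-RMS random
  field multiplied by a temporal AR(1) series, entering multiplicatively as
  a fraction of the signal.

Defaults were chosen once to emulate a realistic, healthy 3 T session and
are not tuned per test: spin-echo 256×256 at 250 mm FOV with σ = 0.7 on
amplitude 100 (SNR ≈ 130–140 as measured over the signal ROI); EPI 64×64 at
220 mm FOV, 200 volumes, σ = 0.25 (SFNR ≈ 400); shading depth 0.3
(PIU ≈ 90 after kernel averaging over the 80% ROI); ghost fraction 0.005
(PSG ≈ 1‰); drift b = 0.004 (≈ 0.4%); coherent amplitude 6·10⁻⁴ with an
8 px correlation length and AR(1) coefficient 0.5 (RDC typically 3–6 and
percent fluctuation ≈ 0.2–0.8‰ — the instability field is a random smooth
surface, so realizations in which it happens to be weak near the phantom
centre behave almost like iid noise and push the RDC toward its upper,
iid limit). Every generator parameter is recoverable by at least
one metric (amplitude/σ by SNR and SFNR, ghost fraction by PSG, shading by
PIU, drift coefficients by drift, coherent amplitude by RDC and
fluctuation), which is what makes the tests parameter-recovery tests rather
than regression snapshots.

What the generator does **not** emulate: k-space acquisition and EPI
trajectories, B0/eddy-current physics, structured artifacts (spikes, RF
interference), receive-chain frequency-response non-uniformity, fat signal,
and multi-coil combination statistics (noise is single-channel complex
Gaussian). Passing tests therefore demonstrate that the *estimators are
correct for the stated measurement model*, not that real scanners satisfy
that model — on real data, e.g., non-central chi backgrounds from multi-coil
reconstruction bias SNR₁ relative to SNR₂, which is precisely the deviation
the SNR ratio flag is designed to surface.

## Units, conventions, degenerate inputs

- PSG and percent fluctuation are defined as percentages but conventionally
  tabulated in per mille; the report stores both keys (`*_percent`,
  `*_permille`, factor 10) to rule out silent unit mistakes.
- Array indexing in the R API is 1-based: the conventional "sixth slice" of
  the structural protocol is `slice = 6` (the default), and the central of
  27 slices is slice 14 (`floor(n/2) + 1`).
- All standard deviations are sample SDs (n−1). Background pixels for SD₁
  pool both FE rectangles into one sample. No outlier rejection is applied
  anywhere: filtering would mask exactly the artifacts PSG and SD-based
  metrics exist to catch.
- Degenerate inputs raise errors at the operation level (zero background SD,
  identical repetitions, empty ROIs, kernels larger than the signal ROI,
  Weisskoff ROIs outside the phantom). The pipeline drivers convert
  *expected* degeneracies — a noiseless synthetic scene has no background SD
  — into `NA` metrics with a warning, so a report can still be written.
- Session summaries use CV = 100·SD/mean with strict `> 10%` flagging, and
  control limits at the grand mean ± 3·SEM, SEM computed from the sample SD
  of (optionally block-averaged, `group_size`) session means; a value is out
  of control only when *strictly* outside the limits, so the zero-width
  degenerate case flags nothing.

## Problem sizes used in validation

The test suite and acceptance script run entirely on simulated scenes at the
protocol's native sizes — 256×256 spin-echo images and 64×64×198-volume EPI
series — with Monte-Carlo loops of 5–50 seeds where sampling distributions
are asserted, and brute-force cross-checks on 8×8 to 48×48 toys where exact
agreement with an independent loop implementation is asserted.

## Known limitations

- DICOM support targets uncompressed little-endian single-frame series with
  standard geometry tags; compressed transfer syntaxes and undefined-length
  sequences are rejected with an explicit error rather than parsed.
- Slice grouping for DICOM series relies on SliceLocation/instance-number
  conventions (slices contiguous within each repetition).
- The phantom detector assumes one circular object; structured phantoms
  (e.g. resolution inserts) and multi-phantom scenes are out of scope.
- The RDC estimate at N = 15 has a sampling SD of roughly 7% at 198 volumes
  even on an ideal scanner; day-to-day RDC scatter of that order is
  expected and should be judged against the control limits, not as a point
  value.
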