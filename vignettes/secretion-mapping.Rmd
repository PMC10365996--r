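---
title: "Methods: label-free single-cell secretion mapping and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free single-cell secretion mapping and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomap)
```

# The measurement model

A gold nanohole array transmits light through an extraordinary-optical-
transmission (EOT) resonance; molecular binding near the surface raises the
local refractive index and redshifts the resonance. When the sensor is
illuminated by a narrowband LED parked on the flank of the resonance line,
a redshift changes the transmitted intensity at each camera pixel, so a
time-lapse intensity stack of a microwell containing a single cell encodes
where and when secreted proteins were captured around that cell. The
package assumes:

* the resonance is well approximated by a Lorentzian line and the shift is
  proportional to the locally bound mass up to surface saturation
  (Langmuir-type capture);
* the reference (empty) microwell shares the global illumination drift and
  noise statistics of its paired sensing well;
* the cell itself only darkens the pixels it covers — its optical
  footprint is handled by masking, not modelling.

# Pipeline stages and their parameters

## Cell segmentation

Each frame is expanded into a **37-channel filter bank**: Gaussian
smoothing at scales 0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0 px, and five
derivative features (Laplacian of Gaussian, Gaussian gradient magnitude,
difference of Gaussians, structure-tensor eigenvalue, Hessian eigenvalue)
at the six scales from 0.7 px up. The two eigenvalue features each
contribute their *largest* eigenvalue only; with both eigenvalues the bank
would hold 43 channels, and the design target is a 37-vector per pixel.
All filters use reflect padding so the well edge does not leak ringing
artefacts into the interior, and the difference of Gaussians compares
scales $\sigma$ and $1.6\sigma$. Filtering is separable and exact — tests
compare it against a dense convolution oracle.

A **random forest with 100 trees** (seeded, default seed 0, recorded in
the classifier object) is trained on sparsely labelled pixels
(0 = unlabelled, 1 = cell, 2 = background) and predicts a background
probability per pixel; 0 means certainly cell. The probability map is
smoothed with a 3×3 arithmetic mean filter — the smallest kernel
consistent with mean filtering, configurable via `filter_radius` — and
thresholded with **Otsu's method** (EBImage's implementation; the test
suite checks it against an exhaustive between-class-variance search).
Pixels *below* the threshold are cell. A constant probability map has no
threshold: the result is an empty mask plus a warning.

Per-frame masks are accumulated into the **cumulative mask**
$C(t)=\bigcup_{s\le t} \mathrm{mask}(s)$, monotone by construction. If a
frame holds several components, the largest is kept; a second component
larger than half the first is retained as a division event. The mean
squared displacement is averaged over the frames after the first, so three
unit steps at 1 µm/px give MSD $=(1+4+9)/3$ µm².

## Secretion mapping

Difference images $\Delta I(t)=|I(t)-I(1)|$ are smoothed with a Gaussian
of $\sigma = 1.5$ px (applied to the difference images, not the raw
frames). The per-frame background level is $\mu + 3\sigma$ of a fixed ROI
in the reference well's difference image (default: a centred 50×50 px
window), subtracted pixel-wise from the sensing difference image and
**clamped at zero** — the clamp makes the $\mu+3\sigma$ level act as a
one-sided noise gate, and under pure Gaussian noise leaves at most ~1.5%
of pixels non-zero (folded-normal tail at the $\mu+3\sigma$ point), which
the tests verify empirically.

The microwell border is found by a **circular Hough transform**: edges are
gradient-magnitude pixels above their Otsu threshold; each candidate
radius accumulates votes by zero-padded FFT correlation with a
one-pixel-wide ring (zero padding prevents wrap-around votes from faking
circles at the border); scores are votes normalised by circumference. Ties
break toward the higher score, then the smaller radius. Detection fails
loudly — with the best score, radius, centre and the edge-pixel count —
when the best score is below 0.25 or below three times the edge density
(the chance level for a dense random edge field).

The analysable region defaults to an **automated annulus**: inside the
well circle eroded by `roi_margin` (5 px), outside the final cumulative
mask dilated by `cell_margin`. The dilation default is
$\lceil 3\sigma\rceil + 2$ px, tied to the smoothing scale: Gaussian
smoothing spreads the (large) cell-motion differences about $3\sigma$
beyond the mask, and a fixed small margin lets that bleed masquerade as
secretion. A user-supplied ROI can override the annulus. Optional
**iterative K-means pruning** (k = 4, minimum size 20 px, distance cutoff
= half the well radius) removes clusters that are both small and far from
the cell centroid, iterating until nothing is removed; pruning is off by
default. Finally the maps are multiplied by the *complement* of the
cumulative mask — interpreted from the stated purpose of removing every
intensity change due to the presence and movement of the cell — so pixels
the cell ever occupied are exactly zero at every frame.

## Kinetics

$\mathrm{TIC}(t)$ sums the non-zero secretion-map pixels (with the
nonnegativity clamp this equals the full-frame sum); the secretion area
multiplies the non-zero count by the physical pixel area
(`object_pixel_size(meta)^2`, µm²). Onset is the first frame with
TIC > 0, optionally required to persist for `persistence` frames
(default 1, the literal rule). A **plateau** starts at the first time
after onset from which three successive steps each stay within
$\varepsilon\cdot\max(\mathrm{TIC})$ ($\varepsilon$ = 0.01 by default;
$\varepsilon = 0$ reproduces the strict "did not increase" rule) and ends
at the first later three-step rise, or at the curve end. Two guards keep
the literal rule usable on sampled noisy curves:

* a plateau may only *start* where the curve has reached at least 20% of
  its maximum (`min_level`); without it, the shallow ramp right after
  onset — whose steps are below $\varepsilon\cdot\max$ simply because the
  signal is still small — reads as a flat triple and turns every type I
  curve into a spurious type III;
* plateau detection needs at least six points from onset, the minimum
  that can bound a flat triple.

Typing follows the plateau: none → **I**; plateau reaching the curve end →
**II**; plateau followed by a rise → **III**. Types I/II are fitted from
onset to the time the curve first reaches 80% of its maximum; type III
gets two fits, onset → 80% of the *plateau mean*, and plateau end → 80% of
the maximum. Slopes are reported per hour regardless of the frame
interval; R² comes from the residual sum of squares (degenerate constant
segments report slope 0, R² 0, and a flag). Duration is the summed length
of the fitted intervals — never the plateau. Fits need at least three
samples; the 80% point is pushed right if necessary to guarantee that.

**Secreting vs non-secreting.** The noise floor is a configurable multiple
(default 5×) of the standard deviation of the residual TIC obtained by
processing a reference well as if it were a sensing well. A cell is called
secreting only when its TIC exceeds that floor in at least
`floor_persistence` (default 3) *consecutive* frames. The sustained
requirement is essential: the clamped residual TIC is a heavy-tailed sum
of rare threshold exceedances, and its maximum over a run regularly
exceeds any small multiple of its standard deviation — but those
exceedances are isolated single-frame blob events, whereas genuinely bound
mass persists from frame to frame. Population summaries use the sample
(n − 1) standard deviation; percentages are reported against the full
population. Apoptosis onset is accepted as an external annotation and
never computed.

# The scene simulator

`simulate_scene()` renders paired sensing/reference stacks with full
ground truth. Defaults are the study conditions: a 200 µm × 50 µm well
(≈1.57 nl) in a 350 px crop at 0.65 µm/px — chosen so the well fits the
crop, since the nominal camera scale (4.25 µm / 20× = 0.2125 µm/px) would
put a 200 µm well far outside a 350 px window — 73 frames at 10 min
(12 h), a 7.5 µm-radius cell 30% darker than the 1000-grey-level
background, executing a seeded random walk rescaled to a 1.3 µm² MSD
(hybridoma-like motility), read noise of 2 grey levels, and a shared
multiplicative drift of 0.1% amplitude with a 600 min period (slow
illumination/thermal drift; exercised separately at larger amplitude in
the drift-tracking tests).

Secretion profiles: `none`, `constant` (type I), `saturating` (type II),
`two_phase` (type III), `burst` and `burst_plus_gradual` (necroptosis-like
release; the burst dumps its mass within `spread_min`, default 10 min).
Each frame's released mass $s(t)\Delta t$ is deposited as an angularly
weighted Gaussian puff centred on the cell with width
$\sigma_s = \sqrt{\sigma_0^2 + 4 D\,\mathrm{age}}$, where *age* is the
time since secretion onset — i.e. the halo of a long-secreting cell keeps
widening diffusively (default $\sigma_0$ = cell radius, D = 0.5 µm²/min,
an effective surface-capture-limited spread, far below free IgG
diffusion). The kernel is normalised over the in-well support, so mass is
conserved exactly before Langmuir limiting; capture is irreversible, each
deposit is scaled by $1 - b/b_{\max}$ and capped at the remaining site
capacity, making the per-pixel bound mass non-decreasing and bounded by
$b_{\max}$. Anisotropic angular weights reproduce C-shaped halos;
isotropic weights give O-shapes.

Transduction integrates a Gaussian LED band (default centred half an FWHM
blue of the resonance — the steepest-slope operating point) against a
Lorentzian line at $\lambda_0$ = 860.7 nm with FWHM 22.6 nm, shifted by
$\Delta\lambda = \Delta\lambda_{\max}\, b/b_{\max}$
($\Delta\lambda_{\max}$ = 15 nm). A documented first-order approximation
(`linear = TRUE`) is selectable, and `transduction_nonlinearity()` reports
the departure of the full integral from it. Division renders an
elongating mother over the two frames before `t_div`, then two separating
daughters, with the affected frames flagged in the ground truth.

**What the simulator does not emulate:** the nanohole texture (below the
rendered resolution; the substrate is uniform), spectral (wavelength-
resolved) read-out, analyte diffusion *after* binding, dissociation,
hydrodynamics, focus drift, and any absolute intensity-to-mass
calibration. Because no calibration links grey levels to molecules, all
quantitative checks are relative — rate *ratios*, durations, type labels,
onsets — never absolute a.u. values. Passing tests therefore demonstrate
that the pipeline recovers what the forward model encodes under realistic
noise, not that it reproduces any particular instrument's absolute
numbers.

# Numerical choices and degenerate inputs

* Kernels are sampled Gaussians with radius $\lceil 3\sigma\rceil$
  (minimum 1); derivative kernels are mean-subtracted so constant images
  map to exactly zero. Images must exceed the widest kernel (49 px with
  the default scales).
* Coordinates are 0-based (row, col), origin top-left; crop windows are
  half-open. Per-frame timestamps, if supplied, override
  index × interval.
* K-means pruning and forest training run under a saved-and-restored RNG
  state, so results are reproducible without disturbing the caller's
  stream.
* Single-frame stacks are readable but refused by difference imaging;
  all-empty masks yield a flagged empty track; curves that never clear
  the noise floor yield NS records with diagnostics rather than errors.
* A reference-level ROI needs at least 4 px; out-of-bounds crops and ROIs
  error rather than clip silently.

# Problem sizes used by the tests

The unit and acceptance tests run desk-scale scenes: 96 px crops at
2.6 µm/px (the same 200 µm well, coarser sampling), 25–60 frames at
2–30 min intervals, 100 scenes for type recovery, 50 null scenes for the
false-call rate, and 100 noisy replicates for the fit-quality bound.
These sizes were chosen as the smallest that keep every geometric feature
(well ring, cell disc, halo) several pixels wide; the generator's defaults
remain the full-scale conditions.

# Known limitations

* The classifier trains on simulator-derived sparse labels in the
  packaged pipeline; on real data a labelled training set (or serialized
  classifier) must be supplied.
* Burst-type curves are typed II/III by the plateau logic — the package
  reports their short fitted durations but does not define a separate
  "burst" class.
* The Hough transform assumes one dominant circle per crop; wells touching
  the crop border are out of scope.
* Absolute secretion quantification (molecules, molarity) requires a
  calibration curve the optical model does not provide.
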