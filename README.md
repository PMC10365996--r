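# secretomap

Spatiotemporal mapping of single-cell protein secretion from label-free
plasmonic microwell time-lapse imaging.

## The problem

Gold nanohole-array sensors support an extraordinary-optical-transmission
(EOT) resonance whose wavelength redshifts when molecules bind near the
surface. Seeding single cells into an array of microwells on such a sensor
and imaging the transmitted intensity of a narrowband near-infrared LED
turns every camera pixel into a local binding sensor: secreted proteins
captured around a cell change the transmitted intensity, frame by frame,
without any fluorescent label. `secretomap` implements the full analysis
chain that turns those raw time-lapse stacks into quantitative single-cell
secretion read-outs, plus a physics-based simulator that generates
ground-truthed synthetic scenes so the whole pipeline can be exercised and
validated without instrument data.

The pipeline, per sensing well (one cell) paired with an empty reference
well:

1. **Cell tracking** — every frame is segmented into cell/background by a
   random forest (100 trees) on a 37-channel multi-scale filter bank
   (Gaussian, Laplacian of Gaussian, gradient magnitude,
   difference-of-Gaussians, structure-tensor and Hessian eigenvalues at
   scales 0.3–10 px). Probability maps are mean-filtered and thresholded by
   Otsu's method; the per-frame masks are accumulated into a cumulative
   mask `C(t) = ∪_{s ≤ t} mask(s)` so every pixel the motile cell ever
   touched is excluded later.
2. **Secretion mapping** — difference imaging `ΔI(t) = |I(t) − I(1)|`
   (Gaussian-smoothed, σ = 1.5 px), background/drift correction by
   pixel-wise subtraction of the reference well's `μ + 3σ` ROI level
   (clamped at 0), restriction to the microwell interior found by a
   circular Hough transform, an automated annulus ROI against edge
   artefacts, optional K-means pruning of small distant clusters, and
   exclusion of the cumulative cell mask. The result is the 4D
   spatiotemporal secretion map `(x, y, ΔI, t)`.
3. **Kinetics** — the total intensity change `TIC(t) = Σ ΔI` over non-zero
   pixels and the secretion area (non-zero pixel count × physical pixel
   area, μm²) are reduced to per-cell kinetics: onset (first TIC > 0),
   plateau detection (no increase over three successive frames, bounded by
   a three-frame rise), linear segment fits from onset to 80% of the
   target level with per-hour slopes and R², secretion typing — **I**
   linear, **II** rise then plateau, **III** rise–plateau–rise (two fits)
   — and population summaries (counts, percentages, mean ± sd).
4. **Simulation** — a `scene_config()` describes a 200 μm × 50 μm well, a
   motile, optionally dividing cell, a secretion profile (constant,
   saturating, two-phase, burst), a diffusion-widened Langmuir-limited
   binding halo, and the optical transduction (Lorentzian EOT line at
   860.7 nm, FWHM 22.6 nm, probed on its flank by a narrowband LED), with
   shared drift and read noise. Ground truth (bound-mass maps, masks,
   event times, type label) is returned alongside the rendered stacks.

## Worked example

Simulate a two-phase (type III) secretor and analyse it end to end:

```r
library(secretomap)

cfg <- scene_config(crop_side = 96, object_pixel_size = 2.6, n_frames = 37,
                    frame_interval = 20,
                    profile = secretion_profile("two_phase", rate = 1,
                                                t_plateau = 240,
                                                t_resume = 480, rate2 = 1.5),
                    seed = 2)
scene <- simulate_scene(cfg)
#> Synthetic scene: 37 frames, label 'III', SNR 307.9

pair <- list(sensing = scene$sensing, reference = scene$reference)
maps <- build_secretion_maps(pair, scene$truth$cell_masks)
#> Well circle: center (47, 48), radius 38 px, score 1.000

tic <- tic_curve(maps)
rec <- classify_and_fit(tic, noise_floor = 10)
rec
#> Kinetics record 'cell': type III
#>   onset 20 min, duration 380 min, max TIC 3.111e+05 a.u.
#>   Linear fit over 20-220 min: slope 1.765e+04 /h, R^2 0.951 (n = 11)
#>   Linear fit over 480-660 min: slope 6.136e+04 /h, R^2 1.000 (n = 10)
```

The cell secreted from the first frame (onset 20 min), rose linearly,
stalled between 240 and 480 min, then resumed faster — the classifier
recovers the configured two-phase ground truth, the two slopes are
reported in arbitrary grey-level units per hour, and the duration (380
min) is the summed length of the two fitted segments, excluding the
plateau. `area_curve()` gives the μm² analogue, `population_summary()`
aggregates many records, and `run_pipeline()` (or the
`inst/scripts/secretomap` CLI) drives the whole chain — including
classifier-based segmentation — writing TIFF/CSV/JSON artefacts and a
manifest.

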