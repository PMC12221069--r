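# twinkledop

Doppler twinkling-artifact imaging for monitoring HIFU thermal lesions from
beamformed RF ultrasound.

High-intensity focused ultrasound (HIFU) coagulates tissue at a focal spot;
guiding it safely needs a real-time readout of where the thermal lesion is and
how big it has grown. Coagulated tissue vibrated by acoustic radiation force
produces the color-Doppler *twinkling artifact* — rapidly alternating Doppler
frequencies not caused by flow. `twinkledop` turns sequences of beamformed
radio-frequency (RF) frames acquired before, during and after a HIFU exposure
into Doppler frequency images that light up the lesion, then segments the
lesion and measures its depth and width in millimetres with summary statistics
against reference dimensions. It is written for ultrasound researchers
prototyping HIFU monitoring on stored RF data.

## Method

At a fixed pixel (scan line, depth sample), the sequence of RF amplitudes
across frames is the *slow-time signal*, sampled at the frame repetition
interval `tPRI`. For a scatterer moving at velocity `v` at angle `θ` to the
beam, the slow-time signal's center frequency is the Doppler shift

    f = 2 v cos θ · fc / c0            (= fD = 2 v f0 cos θ / c0)

with `fc` the imaging pulse center frequency and `c0` the sound speed; the
underlying pulsed-system relations are the inter-pulse delay change
`Δτ = 2 v cos θ · tPRI / c0` and its inverse `v = c0 Δτ / (2 tPRI cos θ)`.

The imaging chain:

1. **Quadrature demodulation** — the analytic signal along fast time, so
   slow-time samples are complex and the sign of the Doppler shift is
   observable.
2. **Sliding windows** — each pixel's slow-time signal is cut into 10-sample
   windows advancing one frame (nine samples of overlap): a 40-frame exposure
   gives 31 windows.
3. **Windowed FFT** — per window, the amplitude, phase and signed frequency
   of the largest non-DC spectral component (the window mean is removed
   first).
4. **Amplitude gating** — a pixel is kept only if its peak amplitude reaches
   one tenth of the window's maximum over the region, suppressing noise.
5. **Phase differencing** — the Doppler frequency of image `k` is the wrapped
   phase difference between consecutive records `k` and `k+1` divided by
   `2π·tPRI`; 31 windows give 30 Doppler images. (The per-window peak bin
   frequency is available as an alternative estimator.)
6. **Lesion measurement** — each Doppler image is median-smoothed,
   thresholded, morphologically closed and reduced to its significant
   4-connected components; the bounding box gives depth and width in mm, and
   per-frame measurements are aggregated into mean, SD, 95% CI, percentage
   error and a one-sample t-test against reference dimensions.

Because the original RF recordings are not public, the package ships a seeded
point-scatterer phantom generator (`phantom_config()`,
`generate_sequence()`) that emulates the acquisition — 81 frames (16 pre /
40 during / 9 post / 16 late) at 250 ms, 6.5 MHz center frequency, with a
lesion whose scatterers jitter during exposure and turn hyperechoic after it
— so the entire chain is testable end to end.

## Worked example

Simulate a 19.25 mm × 13.33 mm field of view (the probe's tissue+lesion
region: 1000 depth samples × 40 lines) holding a 10 mm × 6 mm lesion, run the
monitoring pipeline over the 40 exposure frames, and compare the measured
dimensions with the configured truth:

```r
library(twinkledop)

geom <- acquisition_geometry(n_samples = 1000L, n_lines = 40L,
                             depth_extent_mm = 19.25, width_extent_mm = 13.33,
                             center_freq_hz = 6.5e6)
phantom <- phantom_config(geometry = geom,
                          lesion_center_mm = c(depth = 9.6, width = 6.66),
                          lesion_depth_mm = 10, lesion_width_mm = 6,
                          seed = 1L)
report <- run_pipeline(pipeline_config(phantom = phantom))
print(report)
#> Twinkling-artifact monitoring report (seed 1, phasediff estimator)
#>   30 Doppler images from 81 RF frames
#> Lesion statistics over 30 frames
#>   depth: mean 10.30 mm (ref 10.00), SD 0.04, 95% CI +/- 0.02, err 3.05%, p = 3.42e-27
#>   width: mean 6.00 mm (ref 6.00), SD 0.00, 95% CI +/- 0.00, err 0.03%, p = 0
```

The 30 Doppler images each yield one depth/width measurement
(`report$measurements`); the lesion's 10 mm depth is recovered to ~3% and its
6 mm width to well under 1% for this seed. The tiny p-values flag that the
small systematic bias (axial pulse-length smear) is resolvable at SD ≈ 0.04
mm — statistically detectable, practically negligible.

Lower-level entry points mirror the processing stages: `extract_slow_time()`,
`segment_windows()`, `spectral_peak()`, `build_threshold_mask()`,
`phase_diff_frequency()`, `construct_doppler_frames()`, `segment_lesion()`,
`measure_dimensions()`, `aggregate_stats()`; `doppler_shift_cw()`,
`received_freq()`, `delay_change()` and friends implement the physics
relations. `write_sequence()`/`read_sequence()` store RF stacks as raw
little-endian binary plus a JSON sidecar. A thin command-line wrapper with
`simulate`, `info`, `process`, `measure` and `run` subcommands lives at
`inst/cli/twinkledop.R`.

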