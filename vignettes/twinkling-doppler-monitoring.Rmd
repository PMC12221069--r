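---
title: "Monitoring HIFU thermal lesions with the Doppler twinkling artifact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring HIFU thermal lesions with the Doppler twinkling artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinkledop)
```

## The problem and the signal model

High-intensity focused ultrasound (HIFU) coagulates tissue at a focal spot.
Coagulated tissue has altered acoustic and mechanical properties; under the
acoustic radiation force of the imaging beam it vibrates, and in color
Doppler this produces the *twinkling artifact* — rapidly alternating Doppler
frequencies with no underlying flow. `twinkledop` exploits that artifact as a
lesion marker: pixels inside the lesion acquire broadband slow-time frequency
content during exposure, while static background tissue does not.

The data model is a stack of beamformed radio-frequency (RF) frames,
`[frame, line, sample]`, with geometry (depth/width extents, center frequency
`fc`, sound speed `c0`, fast-time sampling rate) and timing (frame counts of
the pre / during / immediately-post / late-post phases and the inter-frame
interval). The *slow-time signal* at a pixel is its RF amplitude across
frames, sampled at the frame repetition interval `tPRI`. For a scatterer at
velocity `v` and beam-to-motion angle `θ`, successive echoes shift by
`Δτ = 2 v cosθ tPRI / c0`, the slow-time phase advances by `2π fc Δτ` per
frame, and the slow-time center frequency is

$$ f \;=\; \frac{2 v \cos\theta}{c_0} f_c , $$

identical to the continuous-wave Doppler shift
$f_D = 2 v f_0 \cos\theta / c_0$. That identity is what licenses reading the
slow-time spectral peak as the Doppler shift of the RF signal; the
`doppler_params()` functions (`doppler_shift_cw()`, `received_freq()`,
`doppler_shift_exact()`, `delay_change()`, `velocity_from_delay()`,
`slowtime_freq()`) implement the relations and are tested against hand
evaluations and exact algebraic identities.

## The imaging pipeline

1. **Quadrature demodulation** (`analytic = TRUE`). Raw RF slow-time samples
   are real, so their spectrum is conjugate-symmetric and motion *direction*
   is unobservable. We therefore form the analytic (Hilbert) signal along
   fast time before extracting slow-time pixels, the standard pulsed-Doppler
   device for recovering signed shifts. The flag exists so the effect of
   omitting it can be studied.
2. **Sliding windows** (`slowtime_window_spec()`). Default 10 samples per
   window, one-frame step. With the default 40-frame exposure this gives 31
   windows; window length trades frequency resolution (bin width
   `1/(10·tPRI)` = 0.4 Hz at 250 ms) against temporal resolution for
   real-time monitoring.
3. **Windowed spectral peak** (`spectral_peak()`, `spectral_grid()`). Each
   window is demeaned (static echoes otherwise pin the peak at DC — the flag
   `demean` exposes this), FFT'd, and summarised by the largest-magnitude
   non-DC component: amplitude, phase in (−π, π], signed frequency with
   above-Nyquist bins mapped negative. Magnitude ties (e.g. the conjugate
   bins of a real input) resolve to the lowest frequency, positive first, so
   results are deterministic; the comparison uses a 1e−9 relative guard so
   floating-point noise cannot flip a mathematically exact tie.
4. **Amplitude gating** (`build_threshold_mask()`, `ratio = 0.1`). A pixel
   survives if its peak amplitude reaches one tenth of the *reference
   maximum*. We take the reference per window index over the selected region:
   per-pixel normalisation would make the mask vacuous, while a global
   reference over all windows would couple phases of the acquisition; the
   per-window choice suppresses noise relative to the strongest echo of the
   same instant. This scope is an interpretation — the gating rule itself
   only fixes the one-tenth fraction.
5. **Frequency estimation** (`construct_doppler_frames()`). The default
   `phasediff` estimator differences the peak phases of consecutive records,
   wraps into (−π, π], and divides by `2π·dt` with `dt = step · tPRI`:
   31 windows → 30 Doppler images, each bounded by the slow-time Nyquist
   `1/(2·tPRI)` (2 Hz at 250 ms). Wrapping is per pair; no unwrapping across
   pairs is attempted. The alternative `binmax` estimator reports each
   window's peak-bin frequency (31 images); on coherent-motion phantoms the
   two agree within one bin. A pixel gated out in either window of a pair is
   zero in the image.
6. **Lesion segmentation and measurement** (`segment_lesion()`,
   `measure_dimensions()`, `aggregate_stats()`). See below.

## The synthetic phantom

No public RF recordings of this kind of experiment exist, so the package
generates its own (`phantom_config()`, `generate_sequence()`), emulating the
reference acquisition: 81 frames — 16 before, 40 during (250 ms apart, i.e.
a 10 s exposure), 9 immediately after, 16 ten minutes after — on a 4680
sample × 192 line grid spanning 90.10 mm × 64.00 mm at `fc` = 6.5 MHz. The
fast-time rate is derived from the two-way travel time
(`fs = n_samples·c0 / (2·depth)` ≈ 40 MHz at `c0` = 1540 m/s), which is
forced by the stated geometry.

* **Scatterers.** Poisson-counted at `scatterer_density` (default 20/mm²,
  enough axial overlap of neighbouring echoes for contiguous speckle),
  uniform positions, Gaussian reflectivities; each scatterer is assigned to
  the line containing its lateral position. There is no lateral beam spread:
  an echo contributes only to its own line.
* **Pulse.** Gaussian-enveloped cosine at `fc`, 3 cycles FWHM — the simplest
  model consistent with a ~3 MHz bandwidth probe. Echo delays are applied as
  continuous (sub-sample) shifts, since phase-difference estimation lives on
  sub-sample fidelity.
* **Lesion motion.** During exposure the lesion rectangle's scatterers move
  per a `motion_model()`: `coherent` (constant axial velocity, cumulative
  displacement, velocity positive toward the transducer) for parameter
  recovery, or `jitter` — one zero-mean Gaussian axial displacement per
  frame, *shared by all lesion scatterers*. Bulk jitter is our surrogate for
  radiation-force-driven vibration of the coagulated region: the vibration
  amplitude and spectrum are not quantified anywhere we could draw on, so the
  default `jitter_sigma_m` = 20 µm is chosen to give slow-time phase
  excursions of order 1 rad at 6.5 MHz — strong broadband twinkle without
  aliasing artifacts dominating. Per-scatterer independent jitter would
  decorrelate speckle instead; the bulk reading is the physical one (the
  lesion vibrates as a body) and is a single tunable parameter.
* **After exposure** the lesion's scatterers return to rest and their
  amplitude is multiplied by `lesion_echogenicity_gain` (default 2),
  emulating the hyperechoic appearance of coagulated tissue.
* **Noise.** White Gaussian, SD = `noise_sigma` (default 0.05) times the
  noiseless pre-frame RMS.
* **Determinism.** The whole draw happens under `seed`; identical
  configuration and seed give bit-identical sequences.

What the phantom does *not* model: diffraction, focusing, attenuation,
nonlinear propagation, lateral point-spread, lesion growth over the exposure,
HIFU interference (the emulated protocol gates imaging into quiet windows),
or physiological motion. Passing tests on these phantoms therefore show that
the *processing chain* recovers what the signal model puts in — they do not
validate the biological claim that real coagulated tissue twinkles.

## Segmentation: what we chose and why

No canonical rule exists for turning a Doppler frequency map into a lesion
outline, and the obvious one — keep pixels above half the per-image maximum
|f| and take the largest 4-connected component — fails on exactly the signal
the method produces. Twinkling is broadband: per-pixel frequencies spread
over the whole slow-time band and often pile at ±Nyquist, so half-of-max
keeps a ~50%-density speckle mask. That density sits *below* the site
percolation threshold of the square lattice under 4-connectivity (≈ 0.593),
so the "largest component" is a small fragment and the measured box collapses
(we observed 60–90% dimension errors before abandoning it).

The implemented rule (`segment_lesion()`):

1. 3×3 median filter of |f| with edge-replicating borders — removes isolated
   wrapped-phase outliers; a uniform block keeps its bounding box (interior
   corners are shaved, border-abutting ones preserved);
2. threshold at `frac` × the smoothed maximum, with a deliberately small
   default `frac = 0.05`: the lesion outline is already carried by the
   amplitude gate (the method's own noise-removal step), so the |f| cut is
   only a guard against numerically negligible values;
3. 3×3 morphological closing, bridging single-pixel speckle gaps;
4. keep *every* 4-connected component of at least `min_pixels` (default 10)
   pixels — surviving noise specks are far smaller, while demanding the
   single largest component would re-introduce the percolation fragility.

Depth and width are the bounding box of the kept pixels, converted by the
span rule (`n` samples ↔ `n` × mm-per-sample; on the reference grid 1000
samples ↔ 19.25 mm, 40 lines ↔ 13.33 mm). Per-image measurements aggregate
into mean, SD (n−1), 95% CI half-width `t(0.975, n−1)·SD/√n`, percentage
error `|mean − ref|/ref·100`, and a two-sided one-sample t-test p-value
against the reference (the natural reading of a mean-vs-reference
comparison; a zero-SD sample reports p = 1 at the reference and 0 away from
it rather than a degenerate t). Expected residual biases of the pipeline:
the axial box is smeared by roughly the pulse envelope footprint on each
side (~0.2–0.3 mm, a few percent of a centimetre-scale lesion) and
discretised laterally by the line pitch (0.33 mm on the reference grid).

## Numerical and interface choices

* **Indices** are 0-based with half-open ranges everywhere (regions, frame
  selections, window starts), matching the on-disk metadata and making the
  span arithmetic exact; R-side storage is 1-based internally.
* **Windows over phases.** The default analysis covers the 40
  during-exposure frames only; windows never straddle the during→post
  boundary. Any phase or explicit frame set can be selected.
* **On-disk format** (`write_sequence()`/`read_sequence()`): raw
  little-endian binary plus a JSON sidecar naming every geometry/timing
  field; readers report the first missing field by name. Default storage is
  float64 so a write/read round trip is bit-exact; float32 is available
  where the halved size matters.
* **Degenerate inputs.** All-zero windows yield a zero spectral record (not
  NaN); all-zero images yield empty masks and (0, 0) measurements; empty
  regions, out-of-bounds indices, too-few frames and invalid configurations
  raise errors naming the offending field and the required minimum.
* **Problem sizes.** The test-suite and the acceptance script exercise the
  pipeline on phantoms whose field of view is the probe's documented
  tissue+lesion region (1000 samples × 40 lines, 19.25 mm × 13.33 mm) with a
  10 mm × 6 mm lesion — the full 81-frame protocol at the full frame's pixel
  pitch, restricted laterally/axially to where the lesion lives. That keeps
  a ten-phantom accuracy study comfortably inside a coffee break on one core
  while preserving every rate and count of the emulated acquisition.

## Known limitations

* At 250 ms frame spacing the slow-time Nyquist is 2 Hz (≈ 0.24 mm/s at
  6.5 MHz); faster coherent motion aliases, and jitter phantoms routinely
  produce wrapped frequencies — harmless for lesion *extent*, meaningless as
  point velocity estimates.
* The p-values in the aggregate statistics treat the 30 per-image
  measurements as independent; consecutive images share 9 of 10 frames, so
  they are optimistic and should be read as effect-size flags, not inferential
  claims.
* Lateral resolution is the line pitch; sub-line lesion edges are
  unresolvable by construction.
* The phantom validates signal processing, not biology (see above); absolute
  lesion-size claims on real tissue require the original RF data, which is
  not publicly available.
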