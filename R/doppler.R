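#' Doppler physics parameters
#'
#' The constants entering the pulsed-Doppler relations: transmitted/imaging
#' center frequency `f0`, medium sound speed `c0`, beam-motion angle `theta`,
#' and the pulse (here, frame) repetition interval `tPRI` that sets the
#' slow-time sampling rate.
#'
#' @param f0_hz Transmitted / imaging center frequency, Hz.
#' @param c0_m_s Speed of sound in the medium, m/s.
#' @param theta_rad Angle between beam axis and motion, radians.
#' @param t_pri_s Pulse/frame repetition interval, seconds.
#' @return An object of class `doppler_params`.
#' @export
doppler_params <- function(f0_hz = 6.5e6, c0_m_s = 1540, theta_rad = 0,
                           t_pri_s = 0.25) {
  stopifnot(is.numeric(f0_hz), f0_hz > 0,
            is.numeric(c0_m_s), c0_m_s > 0,
            is.numeric(theta_rad),
            is.numeric(t_pri_s), t_pri_s > 0)
  structure(list(f0_hz = f0_hz, c0_m_s = c0_m_s, theta_rad = theta_rad,
                 t_pri_s = t_pri_s),
            class = "doppler_params")
}

#' Continuous-wave Doppler shift
#'
#' The first-order Doppler shift `fD = 2 v f0 cos(theta) / c0` for a scatterer
#' moving at velocity `v` along angle `theta` to the beam.
#'
#' @param v Scatterer velocity, m/s (positive toward the transducer);
#'   `|v| < c0`.
#' @param params A [doppler_params()].
#' @return Doppler shift in Hz.
#' @export
doppler_shift_cw <- function(v, params) {
  stopifnot(inherits(params, "doppler_params"), is.numeric(v))
  if (any(abs(v) >= params$c0_m_s)) {
    stop("|v| must be below the speed of sound", call. = FALSE)
  }
  2 * v * params$f0_hz * cos(params$theta_rad) / params$c0_m_s
}

#' Received frequency and exact Doppler shift of a moving scatterer
#'
#' For pulse-echo reception from a scatterer approaching at `v` (along the
#' beam), the received frequency is `fR = f0 (c + v) / (c - v)` and the exact
#' Doppler shift is `fD = fR - f0 = f0 2 v / (c - v)`. For `v << c` the exact
#' shift agrees with the first-order [doppler_shift_cw()] (at `theta = 0`) to
#' relative order `v / c`.
#'
#' @param v Scatterer velocity, m/s; `|v| < c0`.
#' @param params A [doppler_params()].
#' @return Frequency in Hz.
#' @export
received_freq <- function(v, params) {
  stopifnot(inherits(params, "doppler_params"), is.numeric(v))
  if (any(abs(v) >= params$c0_m_s)) {
    stop("|v| must be below the speed of sound", call. = FALSE)
  }
  params$f0_hz * (params$c0_m_s + v) / (params$c0_m_s - v)
}

#' @rdname received_freq
#' @export
doppler_shift_exact <- function(v, params) {
  received_freq(v, params) - params$f0_hz
}

#' Inter-pulse echo delay change and its inverse
#'
#' A scatterer moving at `v` advances `v cos(theta) t_pri` along the beam
#' between successive transmissions, changing the two-way echo delay by
#' `delta_tau = 2 v cos(theta) t_pri / c0`. `velocity_from_delay()` inverts
#' the relation, `v = c0 delta_tau / (2 t_pri cos(theta))`; the two are exact
#' mutual inverses.
#'
#' @param v Scatterer velocity, m/s.
#' @param delta_tau_s Change in echo delay between successive pulses, seconds.
#' @param params A [doppler_params()]; `cos(theta)` must be nonzero for the
#'   inverse.
#' @return `delay_change()`: delay change in seconds; `velocity_from_delay()`:
#'   velocity in m/s.
#' @export
delay_change <- function(v, params) {
  stopifnot(inherits(params, "doppler_params"), is.numeric(v))
  2 * v * cos(params$theta_rad) * params$t_pri_s / params$c0_m_s
}

#' @rdname delay_change
#' @export
velocity_from_delay <- function(delta_tau_s, params) {
  stopifnot(inherits(params, "doppler_params"), is.numeric(delta_tau_s))
  ct <- cos(params$theta_rad)
  if (abs(ct) < .Machine$double.eps^0.5) {
    stop("velocity is unobservable at theta = pi/2 (cos(theta) = 0)",
         call. = FALSE)
  }
  params$c0_m_s * delta_tau_s / (2 * params$t_pri_s * ct)
}

#' Slow-time (Doppler) frequency of a moving scatterer
#'
#' The center frequency of the slow-time signal sampled at the pulse
#' repetition interval: `f = 2 v cos(theta) fc / c0`, where `fc` is the
#' imaging pulse center frequency (`f0_hz` of the parameters). This is
#' identical to the continuous-wave Doppler shift — the identity that lets
#' the slow-time spectral peak be read as the Doppler shift of the RF signal.
#'
#' @inheritParams doppler_shift_cw
#' @return Slow-time frequency in Hz.
#' @export
slowtime_freq <- function(v, params) {
  doppler_shift_cw(v, params)
}

#' Frequency from the phase difference of consecutive spectral records
#'
#' The Doppler frequency estimator of the imaging pipeline: the phase change
#' between the spectral peaks of two consecutive slow-time windows spaced
#' `dt_s` apart, wrapped into (-pi, pi], divided by `2 pi dt_s`. The result is
#' bounded by the slow-time Nyquist frequency `1 / (2 dt_s)`.
#'
#' @param phase_k,phase_k1 Peak phases (radians) of windows `k` and `k + 1`.
#' @param dt_s Record spacing in seconds (window step times the frame
#'   interval), > 0.
#' @return Estimated frequency in Hz.
#' @export
phase_diff_frequency <- function(phase_k, phase_k1, dt_s) {
  stopifnot(is.numeric(phase_k), is.numeric(phase_k1),
            all(is.finite(phase_k)), all(is.finite(phase_k1)))
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0) {
    stop("dt_s must be a positive number", call. = FALSE)
  }
  wrap_phase(phase_k1 - phase_k) / (2 * pi * dt_s)
}

#' Doppler frequency image for one window (pair)
#'
#' Constructor for the per-window Doppler image: a `(line x sample)` grid of
#' estimated frequency shifts over the selected region, zero wherever the
#' amplitude threshold mask failed.
#'
#' @param freq_hz Numeric matrix `(n_lines x n_samples)` on the region grid.
#' @param window_pair_index 0-based index of the window (pair) the image was
#'   estimated from.
#' @param region The [region_spec()] the image covers.
#' @param geometry The region's [acquisition_geometry()].
#' @param estimator `"phasediff"` or `"binmax"`.
#' @param dt_s Record spacing used by the estimator, seconds.
#' @return An object of class `doppler_image`.
#' @export
doppler_image <- function(freq_hz, window_pair_index, region, geometry,
                          estimator, dt_s) {
  stopifnot(is.matrix(freq_hz), inherits(region, "region_spec"),
            inherits(geometry, "acquisition_geometry"))
  nyq <- 1 / (2 * dt_s)
  if (any(abs(freq_hz) > nyq + 1e-9)) {
    stop("Doppler frequencies exceed the slow-time Nyquist limit ", nyq,
         " Hz", call. = FALSE)
  }
  structure(
    list(freq_hz = freq_hz, window_pair_index = as.integer(window_pair_index),
         region = region, geometry = geometry, estimator = estimator,
         dt_s = dt_s),
    class = "doppler_image"
  )
}

#' @export
print.doppler_image <- function(x, ...) {
  cat(sprintf(
    "Doppler image #%d (%s): %d lines x %d samples, |f| <= %.3g Hz, %d nonzero px\n",
    x$window_pair_index, x$estimator, nrow(x$freq_hz), ncol(x$freq_hz),
    max(abs(x$freq_hz)), sum(x$freq_hz != 0)))
  invisible(x)
}

#' Construct the sequence of Doppler images from an RF sequence
#'
#' Full imaging chain for one acquisition: per-pixel slow-time signals over
#' the selected frames are segmented into sliding windows, each window's
#' spectral peak (amplitude, phase, frequency) is computed, an amplitude
#' threshold mask gates out noise pixels, and per-window Doppler frequency
#' images are formed by one of two estimators:
#' \describe{
#'   \item{`phasediff` (default)}{image `k` is the wrapped phase difference of
#'     consecutive records `k` and `k + 1` divided by `2 pi dt` with
#'     `dt = step * frame_interval`; `n_windows - 1` images (30 at the default
#'     40-frame exposure). A pixel failing the mask in either window of the
#'     pair is zeroed.}
#'   \item{`binmax`}{image `k` is record `k`'s peak bin frequency;
#'     `n_windows` images.}
#' }
#'
#' @param seq An [rf_sequence()].
#' @param region A [region_spec()] or `NULL` for the full frame.
#' @param spec A [slowtime_window_spec()].
#' @param ratio Amplitude threshold fraction (see [build_threshold_mask()]).
#' @param estimator `"phasediff"` or `"binmax"`.
#' @param frames Frame selection as in [resolve_frames()]; default the
#'   during-exposure phase.
#' @param demean Subtract each window's mean before the FFT.
#' @param analytic Fast-time quadrature demodulation before slow-time
#'   extraction (see [spectral_grid()]); default `TRUE`.
#' @return List of [doppler_image()] objects, in window order.
#' @export
construct_doppler_frames <- function(seq, region = NULL,
                                     spec = slowtime_window_spec(),
                                     ratio = 0.1,
                                     estimator = c("phasediff", "binmax"),
                                     frames = "during", demean = TRUE,
                                     analytic = TRUE) {
  estimator <- match.arg(estimator)
  idx <- resolve_frames(seq, frames)
  min_needed <- spec$window_len + if (estimator == "phasediff") spec$step else 0L
  if (length(idx) < min_needed) {
    stop("need at least ", min_needed, " frames for the ", estimator,
         " estimator (window ", spec$window_len, ", step ", spec$step,
         "); got ", length(idx), call. = FALSE)
  }
  grid <- spectral_grid(seq, region, spec, frames = idx, demean = demean,
                        analytic = analytic)
  mask <- build_threshold_mask(grid, ratio)$mask
  nw <- dim(grid$amplitude)[1]
  nl <- dim(grid$amplitude)[2]
  ns <- dim(grid$amplitude)[3]
  reg <- grid$region
  out <- list()
  if (estimator == "phasediff") {
    for (k in seq_len(nw - 1L)) {
      f <- phase_diff_frequency(matrix(grid$phase[k, , ], nl, ns),
                                matrix(grid$phase[k + 1L, , ], nl, ns),
                                grid$dt_s)
      ok <- matrix(mask[k, , ] & mask[k + 1L, , ], nl, ns)
      f[!ok] <- 0
      out[[k]] <- doppler_image(f, k - 1L, reg, grid$geometry, estimator,
                                grid$dt_s)
    }
  } else {
    for (k in seq_len(nw)) {
      f <- matrix(grid$freq[k, , ], nl, ns)
      f[!matrix(mask[k, , ], nl, ns)] <- 0
      # bin frequencies are bounded by the per-frame Nyquist, not the
      # (possibly longer) record spacing
      out[[k]] <- doppler_image(f, k - 1L, reg, grid$geometry, estimator,
                                grid$frame_interval_s)
    }
  }
  out
}
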