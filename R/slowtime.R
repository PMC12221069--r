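#' Sliding-window specification for slow-time analysis
#'
#' Slow-time signals (one RF amplitude per frame at a fixed pixel) are cut
#' into overlapping windows before spectral estimation. The defaults — 10
#' samples per window advancing one frame at a time, i.e. nine samples of
#' overlap — trade frequency resolution against the temporal resolution
#' needed for real-time lesion monitoring: a 40-frame exposure yields 31
#' windows and hence 30 consecutive window pairs.
#'
#' @param window_len Samples per window (>= 1).
#' @param step Window advance in frames (>= 1).
#' @return An object of class `slowtime_window_spec`.
#' @export
slowtime_window_spec <- function(window_len = 10L, step = 1L) {
  stopifnot(is.numeric(window_len), length(window_len) == 1L, window_len >= 1,
            window_len == floor(window_len),
            is.numeric(step), length(step) == 1L, step >= 1,
            step == floor(step))
  structure(list(window_len = as.integer(window_len), step = as.integer(step)),
            class = "slowtime_window_spec")
}

#' Number of windows for a signal length
#'
#' `floor((len - window_len) / step) + 1`, exact for all valid inputs.
#'
#' @param len Signal length in samples (>= `spec$window_len`).
#' @param spec A [slowtime_window_spec()].
#' @return Integer window count.
#' @export
n_windows <- function(len, spec) {
  stopifnot(inherits(spec, "slowtime_window_spec"))
  if (len < spec$window_len) {
    stop("signal length ", len, " is shorter than the window length ",
         spec$window_len, call. = FALSE)
  }
  as.integer((len - spec$window_len) %/% spec$step) + 1L
}

#' Extract the slow-time signal at one pixel
#'
#' The slow-time signal is the sequence of RF amplitudes at a fixed
#' (line, sample) position across successive frames — the sampled signal from
#' a specific depth in a sequence of RF lines. During a 10-second exposure
#' imaged at 250 ms intervals it has 40 samples.
#'
#' @param seq An [rf_sequence()].
#' @param line 0-based scan line index.
#' @param sample 0-based fast-time sample index.
#' @param frames Frame selection as in [resolve_frames()] (phase label,
#'   0-based indices, or `NULL` for all frames).
#' @return Numeric vector in frame order.
#' @export
extract_slow_time <- function(seq, line, sample, frames = NULL) {
  stopifnot(inherits(seq, "rf_sequence"),
            is.numeric(line), length(line) == 1L,
            is.numeric(sample), length(sample) == 1L)
  d <- dim(seq$data)
  if (line < 0 || line >= d[2]) {
    stop("line index ", line, " out of range [0, ", d[2] - 1L, "]",
         call. = FALSE)
  }
  if (sample < 0 || sample >= d[3]) {
    stop("sample index ", sample, " out of range [0, ", d[3] - 1L, "]",
         call. = FALSE)
  }
  idx <- resolve_frames(seq, frames)
  seq$data[idx + 1L, line + 1L, sample + 1L]
}

#' Segment a slow-time signal into sliding windows
#'
#' @param signal Numeric vector of length >= `spec$window_len`.
#' @param spec A [slowtime_window_spec()].
#' @return List of numeric windows; window `k` (1-based list position) starts
#'   at 0-based sample `(k - 1) * step`.
#' @export
segment_windows <- function(signal, spec = slowtime_window_spec()) {
  stopifnot(is.numeric(signal))
  nw <- n_windows(length(signal), spec)
  lapply(seq_len(nw), function(k) {
    start <- (k - 1L) * spec$step
    signal[(start + 1L):(start + spec$window_len)]
  })
}

# Analytic (Hilbert) signal of each column of a real matrix: FFT along the
# column, zero the negative-frequency half (DC and Nyquist kept at unit
# weight), inverse FFT. Fast-time quadrature demodulation — the step that
# makes slow-time samples complex so that Doppler direction is observable.
.analytic_columns <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n %/% 2 + 1L)] <- 1
    h[2L:(n %/% 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2)] <- 2
  }
  stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
}

# Non-DC bin frequencies of an N-point DFT at sampling interval dt, as signed
# frequencies (bins above Nyquist map to negative), together with the scan
# order used for peak picking: ascending |f|, positive before negative, so the
# lowest-frequency bin wins magnitude ties deterministically.
.dft_bins <- function(n, dt) {
  k <- seq_len(n - 1L)                      # 0-based non-DC bins 1..n-1
  f <- ifelse(k <= n %/% 2, k, k - n) / (n * dt)
  ord <- order(abs(f), -f)
  list(bin = k[ord], freq = f[ord])
}

# Core spectral-peak estimator on a window matrix (window_len x n_pixels).
# Returns amplitude, phase (in (-pi, pi]), and signed frequency of the
# largest-magnitude non-DC DFT component per column. All-zero (after optional
# demeaning) columns get amplitude 0, phase 0, frequency 0.
.spectral_peak_matrix <- function(segmat, dt, demean = TRUE) {
  n <- nrow(segmat)
  if (demean) segmat <- sweep(segmat, 2L, colMeans(segmat))
  sp <- stats::mvfft(segmat)
  bins <- .dft_bins(n, dt)
  p <- ncol(segmat)
  b1 <- bins$bin[1L] + 1L
  best <- sp[b1, ]
  best_mag <- Mod(best)
  best_freq <- rep(bins$freq[1L], p)
  for (j in seq_along(bins$bin)[-1L]) {
    row <- bins$bin[j] + 1L
    mag <- Mod(sp[row, ])
    # strictly greater up to floating noise, so exact magnitude ties (e.g.
    # conjugate bins of a real signal) resolve to the lowest-frequency bin
    upd <- mag > best_mag * (1 + 1e-9)
    if (any(upd)) {
      best[upd] <- sp[row, upd]
      best_mag[upd] <- mag[upd]
      best_freq[upd] <- bins$freq[j]
    }
  }
  phase <- wrap_phase(Arg(best))
  zero <- best_mag == 0
  phase[zero] <- 0
  best_freq[zero] <- 0
  list(amplitude = best_mag, phase = phase, freq = best_freq)
}

#' Spectral peak of one slow-time window
#'
#' Optionally removes the window mean (default: static echoes dominate
#' slow-time signals, so without demeaning the peak would always sit at DC),
#' computes the discrete Fourier transform, and returns the amplitude, phase,
#' and signed frequency of the largest-magnitude non-DC component. Bin
#' frequencies are `bin / (window_len * frame_interval_s)` with bins above
#' Nyquist mapped to negative frequencies; magnitude ties go to the
#' lowest-frequency bin (positive before negative). An all-zero window yields
#' amplitude 0 with phase and frequency defined as 0.
#'
#' @param window Numeric vector, length >= 2.
#' @param frame_interval_s Slow-time sampling interval, seconds.
#' @param demean Subtract the window mean first (default `TRUE`).
#' @param window_index 0-based frame index of the window's first sample,
#'   carried through for bookkeeping.
#' @return An object of class `spectral_record`: a list with
#'   `peak_amplitude`, `peak_phase_rad` (in (-pi, pi]), `peak_freq_hz`
#'   (within the slow-time Nyquist `1 / (2 frame_interval_s)`), and
#'   `window_index`.
#' @export
spectral_peak <- function(window, frame_interval_s, demean = TRUE,
                          window_index = 0L) {
  stopifnot(is.numeric(window) || is.complex(window), length(window) >= 2L,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  r <- .spectral_peak_matrix(matrix(window, ncol = 1L), frame_interval_s,
                             demean)
  structure(
    list(peak_amplitude = r$amplitude[1L], peak_phase_rad = r$phase[1L],
         peak_freq_hz = r$freq[1L], window_index = as.integer(window_index)),
    class = "spectral_record"
  )
}

#' Windowed spectral records for every pixel of a region
#'
#' Runs the sliding-window spectral-peak estimator at every (line, sample)
#' pixel of the selected region over the selected frames. This is the tensor
#' of per-window peak amplitude / phase / frequency from which threshold masks
#' and Doppler images are built.
#'
#' @param seq An [rf_sequence()].
#' @param region A [region_spec()], or `NULL` for the full frame.
#' @param spec A [slowtime_window_spec()].
#' @param frames Frame selection as in [resolve_frames()]; default `"during"`.
#' @param demean Subtract each window's mean (default `TRUE`).
#' @param analytic Apply fast-time quadrature (analytic-signal) demodulation
#'   before extracting slow-time signals (default `TRUE`). With real RF
#'   samples the slow-time spectrum is conjugate-symmetric and motion
#'   direction is unobservable; the analytic signal makes slow-time samples
#'   complex so that the sign of the Doppler shift is preserved.
#' @return An object of class `spectral_grid`: arrays `amplitude`, `phase`,
#'   `freq` of dimension `(n_windows, n_lines, n_samples)` over the region
#'   grid, plus `window_starts` (0-based first-frame index of each window
#'   within the selected frames), `dt_s` (record spacing,
#'   `step * frame_interval_s`), `spec`, `region`, and the region `geometry`.
#' @export
spectral_grid <- function(seq, region = NULL, spec = slowtime_window_spec(),
                          frames = "during", demean = TRUE, analytic = TRUE) {
  stopifnot(inherits(seq, "rf_sequence"))
  if (is.null(region)) {
    region <- region_spec(0L, seq$geometry$n_samples, 0L, seq$geometry$n_lines)
  }
  sub <- select_region(seq, region)
  idx <- resolve_frames(seq, frames)
  nf <- length(idx)
  nw <- n_windows(nf, spec)                 # errors if too few frames
  nl <- sub$geometry$n_lines
  ns <- sub$geometry$n_samples
  arr <- sub$data[idx + 1L, , , drop = FALSE]
  if (analytic && ns >= 2L) {
    a3 <- aperm(arr, c(3L, 1L, 2L))         # ns x nf x nl
    ac <- .analytic_columns(matrix(a3, ns, nf * nl))
    arr <- aperm(array(ac, dim = c(ns, nf, nl)), c(2L, 3L, 1L))
  }
  m <- matrix(arr, nf, nl * ns)
  dt <- spec$step * seq$timing$frame_interval_s
  amp <- array(0, dim = c(nw, nl, ns))
  ph <- array(0, dim = c(nw, nl, ns))
  fr <- array(0, dim = c(nw, nl, ns))
  for (k in seq_len(nw)) {
    start <- (k - 1L) * spec$step
    seg <- m[(start + 1L):(start + spec$window_len), , drop = FALSE]
    r <- .spectral_peak_matrix(seg, seq$timing$frame_interval_s, demean)
    amp[k, , ] <- r$amplitude
    ph[k, , ] <- r$phase
    fr[k, , ] <- r$freq
  }
  structure(
    list(amplitude = amp, phase = ph, freq = fr,
         window_starts = (seq_len(nw) - 1L) * spec$step,
         dt_s = dt, frame_interval_s = seq$timing$frame_interval_s,
         spec = spec, region = region, geometry = sub$geometry,
         analytic = analytic),
    class = "spectral_grid"
  )
}

#' Amplitude threshold mask over a spectral grid
#'
#' Noise gating: for each window index, the reference maximum is the largest
#' peak amplitude over all pixels of the region in that window, and a pixel
#' passes when its peak amplitude is at least `ratio` times that reference.
#' The default one-tenth ratio suppresses weak noise pixels relative to the
#' strongest echo while keeping the lesion's broadband response. Raising the
#' ratio can only shrink the mask (monotonicity).
#'
#' @param records A [spectral_grid()].
#' @param ratio Threshold fraction in `[0, 1]`.
#' @return An object of class `threshold_mask`: logical array of the grid's
#'   dimensions plus the `ratio` used.
#' @export
build_threshold_mask <- function(records, ratio = 0.1) {
  stopifnot(inherits(records, "spectral_grid"),
            is.numeric(ratio), length(ratio) == 1L, ratio >= 0, ratio <= 1)
  amp <- records$amplitude
  nw <- dim(amp)[1]
  mask <- array(FALSE, dim = dim(amp))
  for (k in seq_len(nw)) {
    ref <- max(amp[k, , ])
    mask[k, , ] <- amp[k, , ] >= ratio * ref
  }
  structure(list(mask = mask, ratio = ratio), class = "threshold_mask")
}
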