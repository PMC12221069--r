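# Shared fixtures and independent brute-force oracles.

# Reference probe geometry (endocavity array: 4680 samples over 90.10 mm,
# 192 lines over 64.00 mm, 6.5 MHz).
table_geometry <- function() {
  acquisition_geometry(4680L, 192L, 90.10, 64.00, 6.5e6)
}

# Small geometry preserving the reference per-sample/per-line pitches and the
# ~40 MHz sampling rate, for fast unit tests.
tiny_geometry <- function(ns = 200L, nl = 16L) {
  acquisition_geometry(ns, nl, ns * 90.10 / 4680, nl * 64.00 / 192, 6.5e6)
}

# Desk-scale phantom whose field of view is the selected tissue+lesion region
# (1000 samples x 40 lines = 19.25 mm x 13.33 mm) with a known 10 x 6 mm
# lesion rectangle; the configuration used for end-to-end accuracy checks.
desk_phantom <- function(seed, lesion_motion = motion_model("jitter"),
                         noise_sigma = 0.05, ...) {
  phantom_config(
    geometry = acquisition_geometry(1000L, 40L, 19.25, 13.33, 6.5e6),
    lesion_center_mm = c(depth = 9.6, width = 6.66),
    lesion_depth_mm = 10, lesion_width_mm = 6,
    lesion_motion = lesion_motion, noise_sigma = noise_sigma,
    seed = seed, ...
  )
}

# 1-based index ranges of the desk phantom's true lesion rectangle on the
# line x sample grid (depth 4.6..14.6 mm, lateral 3.66..9.66 mm).
desk_lesion_lines <- 12:29
desk_lesion_samples <- 240:758

# Brute-force DFT by direct summation; returns per-bin signed frequency,
# magnitude and phase. Independent of the package's FFT path.
brute_dft <- function(x, dt) {
  n <- length(x)
  k <- 0:(n - 1)
  res <- t(vapply(k, function(kk) {
    s <- sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
    c(Mod(s), Arg(s))
  }, numeric(2)))
  freq <- ifelse(k <= n %/% 2, k, k - n) / (n * dt)
  data.frame(bin = k, freq = freq, amp = res[, 1], phase = res[, 2])
}

# Brute-force spectral peak: demean, drop DC, pick the max-magnitude bin with
# ties going to the lowest |freq| (positive first).
brute_spectral_peak <- function(x, dt) {
  d <- brute_dft(x - mean(x), dt)
  d <- d[d$bin != 0, ]
  d <- d[order(abs(d$freq), -d$freq), ]
  best <- d[which.max(d$amp > max(d$amp) - 1e-12), ]  # first max under ties
  best
}

# Brute-force 4-connected labelling by iterative label propagation.
brute_label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj] &&
            lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# Brute-force 3x3 median filter with clamped (edge-replicating) borders.
brute_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-1):1, 1), nr)
    jj <- pmin(pmax(j + (-1):1, 1), nc)
    out[i, j] <- stats::median(as.vector(m[ii, jj]))
  }
  out
}

# Envelope of a real RF line via the analytic signal (independent small
# implementation for echo-position oracles).
envelope_of <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
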