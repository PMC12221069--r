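test_that("slow-time extraction returns the per-frame pixel values", {
  g <- tiny_geometry(20L, 3L)
  t <- acquisition_timing(2L, 11L, 1L, 1L)
  n <- n_frames_total(t)
  data <- array(0, dim = c(n, 3, 20))
  vals <- seq_len(n) * 1.5
  data[, 2, 7] <- vals
  s <- rf_sequence(data, g, t)
  expect_identical(extract_slow_time(s, 1, 6), vals)
  during <- extract_slow_time(s, 1, 6, frames = "during")
  expect_identical(during, vals[3:13])
  expect_identical(length(extract_slow_time(s, 0, 0, frames = "during")), 11L)
  expect_error(extract_slow_time(s, 3, 0), "line index")
  expect_error(extract_slow_time(s, 0, 20), "sample index")
  # constant stack -> constant signal
  s2 <- rf_sequence(array(2, dim = c(n, 3, 20)), g, t)
  expect_identical(extract_slow_time(s2, 0, 0), rep(2, n))
})

test_that("window segmentation follows the count formula", {
  spec <- slowtime_window_spec(10L, 1L)
  w <- segment_windows(seq_len(40), spec)
  expect_identical(length(w), 31L)
  expect_identical(w[[1]], 1:10)
  expect_identical(w[[31]], 31:40)
  expect_identical(segment_windows(seq_len(10), spec)[[1]], 1:10)
  expect_identical(length(segment_windows(seq_len(10), spec)), 1L)
  expect_error(segment_windows(seq_len(9), spec), "shorter")
  # formula exact across (len, window_len, step)
  for (len in c(10, 17, 40)) for (wl in c(2, 5, 10)) for (st in c(1, 2, 3)) {
    sp <- slowtime_window_spec(wl, st)
    expect_identical(n_windows(len, sp),
                     as.integer(floor((len - wl) / st) + 1))
    expect_identical(length(segment_windows(seq_len(len), sp)),
                     n_windows(len, sp))
  }
})

test_that("spectral peaks match the brute-force DFT oracle", {
  dt <- 0.25
  tt <- (0:9) * dt
  # exact-bin sinusoid: frequency and phase recovered
  for (phi0 in c(-2.1, -0.4, 0.9, 2.8)) {
    x <- cos(2 * pi * 0.8 * tt + phi0)
    r <- spectral_peak(x, dt)
    expect_equal(r$peak_freq_hz, 0.8)
    expect_equal(r$peak_phase_rad, phi0, tolerance = 1e-8)
  }
  # off-bin and random signals agree with the oracle
  set.seed(33)
  cases <- c(list(cos(2 * pi * 1 * tt)),
             lapply(1:6, function(i) rnorm(10)))
  for (x in cases) {
    r <- spectral_peak(x, dt)
    o <- brute_spectral_peak(x, dt)
    expect_equal(r$peak_freq_hz, o$freq)
    expect_equal(r$peak_amplitude, o$amp, tolerance = 1e-9)
    expect_lte(abs(r$peak_freq_hz), 1 / (2 * dt))
    expect_true(r$peak_phase_rad > -pi && r$peak_phase_rad <= pi)
  }
  # all-zero and constant (demeaned) windows give a zero record
  z <- spectral_peak(rep(0, 10), dt)
  expect_identical(c(z$peak_amplitude, z$peak_phase_rad, z$peak_freq_hz),
                   c(0, 0, 0))
  cst <- spectral_peak(rep(3.7, 10), dt)
  expect_equal(cst$peak_amplitude, 0, tolerance = 1e-12)
  # without demeaning, the DC-dominated constant window peaks off-DC at the
  # leakage floor but with tiny amplitude relative to the demeaned sinusoid
  expect_error(spectral_peak(1, dt), "length")
})

test_that("the threshold mask applies the stated rule and is monotone", {
  # hand grid: one window, amplitudes {10, 2, 0.5}
  g <- tiny_geometry(3L, 1L)
  t <- acquisition_timing(0L, 12L, 0L, 0L)
  data <- array(0, dim = c(12, 1, 3))
  # sinusoids of different amplitudes at the same bin frequency
  tt <- (0:11) * 0.25
  for (j in 1:3) data[, 1, j] <- c(10, 2, 0.5)[j] * cos(2 * pi * 1 * tt)
  s <- rf_sequence(data, g, t)
  grid <- spectral_grid(s, spec = slowtime_window_spec(12L, 1L),
                        frames = "during", analytic = FALSE)
  m1 <- build_threshold_mask(grid, 0.1)
  expect_identical(as.vector(m1$mask[1, 1, ]), c(TRUE, TRUE, FALSE))
  expect_true(all(build_threshold_mask(grid, 0)$mask))
  expect_identical(as.vector(build_threshold_mask(grid, 1)$mask[1, 1, ]),
                   c(TRUE, FALSE, FALSE))
  # monotone: raising the ratio never turns a pixel on
  ratios <- c(0, 0.05, 0.1, 0.3, 0.6, 1)
  masks <- lapply(ratios, function(r) build_threshold_mask(grid, r)$mask)
  for (i in seq_along(ratios)[-1]) {
    expect_true(all(masks[[i]] <= masks[[i - 1]]))
  }
})

test_that("spectral grids carry per-window records on the region grid", {
  cfg <- phantom_config(geometry = tiny_geometry(200L, 8L),
                        timing = acquisition_timing(2L, 14L, 1L, 1L),
                        lesion_center_mm = c(depth = 2, width = 1.3),
                        lesion_depth_mm = 1.4, lesion_width_mm = 1.2,
                        seed = 13L)
  s <- generate_sequence(cfg)
  reg <- region_spec(40, 160, 1, 7)
  grid <- spectral_grid(s, reg, slowtime_window_spec(10L, 1L))
  expect_identical(dim(grid$amplitude), c(5L, 6L, 120L))
  expect_identical(grid$window_starts, 0:4)
  expect_equal(grid$dt_s, 0.25)
  expect_true(all(abs(grid$freq) <= 2))
  expect_true(all(grid$phase > -pi & grid$phase <= pi))
})
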