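test_that("rectification is the elementwise absolute value", {
  rec <- tibble::tibble(time_ms = c(0, 1, 2), a = c(-1, 2, -3), b = c(0, -1, 1))
  out <- rectify(rec)
  expect_equal(out$a, c(1, 2, 3))
  expect_equal(out$b, c(0, 1, 1))
  expect_identical(rectify(out), out)  # idempotent on nonnegative input
})

test_that("rectified zero-mean noise has the half-normal mean", {
  sigma <- 0.7
  set.seed(1)
  rec <- tibble::tibble(time_ms = seq_len(2e5) - 1,
                        x = rnorm(2e5, 0, sigma))
  expect_equal(mean(rectify(rec)$x), sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("the Butterworth low-pass has the definitional gains", {
  fs <- 2000
  t_s <- seq(0, 20, by = 1 / fs)
  rec <- tibble::tibble(time_ms = t_s * 1000,
                        dc = rep(2.5, length(t_s)),
                        f4 = sin(2 * pi * 4 * t_s),
                        f100 = sin(2 * pi * 100 * t_s))
  out <- lowpass(rec, cutoff = 4, order = 2)
  steady <- out[t_s > 5, ]
  expect_equal(mean(steady$dc), 2.5, tolerance = 1e-6)       # DC gain 1
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_equal(amp(steady$f4), 1 / sqrt(2), tolerance = 0.02)  # -3 dB at fc
  # second-order roll-off: |H(100)| = 1/sqrt(1 + (100/4)^4) ~ 1.6e-3
  expect_equal(amp(steady$f100), 1.6e-3, tolerance = 0.15)
  expect_error(lowpass(rec, cutoff = 1000), "Nyquist")
})

test_that("zero-phase filtering leaves a constant untouched away from edges", {
  rec <- tibble::tibble(time_ms = seq(0, 19999) / 2, x = rep(1, 20000))
  out <- lowpass(rec, zero_phase = TRUE)
  expect_equal(mean(out$x[5000:15000]), 1, tolerance = 1e-6)
})

test_that("decimation subsamples to the requested rate", {
  rec <- tibble::tibble(time_ms = seq(0, 1999) * 0.5, x = seq_len(2000))
  out <- decimate(rec, to = 100)
  expect_equal(rec_fs(out), 100)
  expect_equal(out$x[1:3], c(1, 21, 41))
})

test_that("channel QC drops near-noise channels and keeps active ones", {
  cfg <- cohort_config(n_subjects = 1, sample_rate = 500,
                       include_noise_channels = TRUE, seed = 8)
  recs <- list(generate_recording(cfg, default_trend(), 1, 1, 20),
               generate_recording(cfg, default_trend(), 1, 1, 0))
  kept <- channel_qc(recs)
  expect_setequal(kept, MUSC)   # MG and TA discarded

  strong <- make_burst_recording(channels = c("a", "b", "c"))
  expect_setequal(channel_qc(strong), c("a", "b", "c"))
  expect_setequal(channel_qc(strong, snr_threshold = 0), c("a", "b", "c"))

  flat <- tibble::tibble(time_ms = seq(0, 1999) * 2,
                         a = rnorm(2000), b = rnorm(2000))
  expect_error(channel_qc(flat), "fewer than 2")
})

test_that("burst segmentation recovers generator onsets within 250 ms", {
  cfg <- cohort_config(n_subjects = 1, sample_rate = 500, seed = 21)
  for (cond in list(c(1, 0), c(2, 20))) {
    rec <- generate_recording(cfg, default_trend(), 1, cond[1], cond[2])
    truth <- attr(rec, "truth")
    segs <- segment_bursts(rectify(rec), expected = cfg$bursts_per_condition)
    onsets <- vapply(segs, attr, numeric(1), "onset_ms")
    expect_length(segs, 6)
    expect_true(all(abs(onsets - truth$onsets_ms) <= 250))
    # equal-length windows
    expect_length(unique(vapply(segs, nrow, integer(1))), 1)
  }
})

test_that("segmentation handles single bursts and degenerate input", {
  rec <- make_burst_recording(seed = 3)
  segs <- segment_bursts(rectify(rec), expected = 1)
  expect_length(segs, 1)
  # the plateau (centre of the burst) is inside the window
  seg <- segs[[1]]
  expect_true(min(seg$time_ms) < 5500 && max(seg$time_ms) > 5500)

  flat <- tibble::tibble(time_ms = seq(0, 4999) * 2, RF = rep(0, 5000))
  expect_error(segment_bursts(flat, expected = 6), "no bursts")

  cfg <- cohort_config(n_subjects = 1, sample_rate = 500, seed = 4)
  rec6 <- generate_recording(cfg, default_trend(), 1, 1, 0)
  expect_error(segment_bursts(rectify(rec6), expected = 3), "expected 3")
})

test_that("burst normalization scales rows to unit maximum", {
  D <- rbind(a = c(0, 2, 4), b = c(1, 1, 1), z = c(0, 0, 0))
  out <- normalize_burst(D)
  expect_equal(out["a", ], c(0, 0.5, 1))
  expect_equal(out["b", ], c(1, 1, 1))
  expect_equal(out["z", ], c(0, 0, 0))        # no division error
  expect_identical(normalize_burst(out), out)  # idempotent
  expect_error(normalize_burst(rbind(c(-1, 1))), "nonnegative")
})

test_that("burst_matrix stacks channels in row order with metadata", {
  rec <- make_burst_recording(fs = 100, channels = c("RF", "VL"))
  D <- burst_matrix(rectify(rec))
  expect_equal(rownames(D), c("RF", "VL"))
  expect_equal(ncol(D), nrow(rec))
  expect_false(attr(D, "normalized"))
  expect_equal(attr(D, "fs"), 100)
})
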