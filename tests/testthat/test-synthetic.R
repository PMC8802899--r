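test_that("the cohort has the experiment's structure", {
  cfg <- cohort_config()
  conds <- cohort_conditions(cfg)
  expect_equal(nrow(conds), 17 * 2 * 4)
  # 816 bursts per muscle in total
  expect_equal(nrow(conds) * cfg$bursts_per_condition, 816)

  tiny <- cohort_config(n_subjects = 1, positions = 1, angles = 0,
                        sample_rate = 250, seed = 2)
  rec <- generate_recording(tiny, default_trend(), 1, 1, 0)
  segs <- segment_bursts(rectify(rec), expected = 6)
  expect_length(segs, 6)
})

test_that("the default trend satisfies its structural invariants", {
  trend <- default_trend()
  expect_length(validate_trend(trend), 0)
  a <- function(m, p) {
    rows <- trend$table[trend$table$muscle == m & trend$table$position == p, ]
    setNames(rows$a[order(rows$angle)], sort(unique(rows$angle)))
  }
  expect_true(a("VM", 1)["0"] > a("VM", 1)["20"] &&
                a("VM", 1)["20"] > a("VM", 1)["60"])
  expect_gt(a("RF", 1)["60"], a("RF", 2)["60"])
  # position 2: no meaningful drop beyond 20 degrees
  expect_lt(a("VM", 2)["20"] - a("VM", 2)["60"], 0.05)

  broken <- trend
  broken$table$a[broken$table$muscle == "VL" & broken$table$position == 1 &
                   broken$table$angle == 20] <- 1.2
  expect_gt(length(validate_trend(broken)), 0)
})

test_that("bursts are reproducible and have the half-normal plateau mean", {
  cfg <- cohort_config(drift_sd = 0, seed = 1)
  trend <- default_trend()
  b1 <- generate_burst(trend, "RF", 0, 1, cfg, seed = 11)
  b2 <- generate_burst(trend, "RF", 0, 1, cfg, seed = 11)
  expect_identical(b1$value, b2$value)
  truth <- attr(b1, "truth")
  plateau <- b1$value[b1$time_ms > truth$onset_ms + 1000 &
                        b1$time_ms < truth$onset_ms + 500 + 5000]
  expect_equal(mean(abs(plateau)), truth$plateau * sqrt(2 / pi),
               tolerance = 0.05)

  silent <- trend
  silent$table$a <- 0
  silent$table$b <- 0
  b0 <- generate_burst(silent, "RF", 0, 1, cfg, seed = 1)
  expect_true(all(b0$value == 0))
})

test_that("cohort recordings are deterministic in the seed", {
  cfg <- cohort_config(n_subjects = 1, sample_rate = 250, seed = 9)
  r1 <- generate_recording(cfg, default_trend(), 1, 2, 60)
  r2 <- generate_recording(cfg, default_trend(), 1, 2, 60)
  expect_identical(r1, r2)
  cfg2 <- cohort_config(n_subjects = 1, sample_rate = 250, seed = 10)
  r3 <- generate_recording(cfg2, default_trend(), 1, 2, 60)
  expect_false(identical(r1$RF, r3$RF))
})

test_that("the optional MG/TA channels are discarded by channel QC", {
  cfg <- cohort_config(n_subjects = 1, sample_rate = 500,
                       include_noise_channels = TRUE, seed = 12)
  recs <- lapply(c(0, 20), function(a)
    generate_recording(cfg, default_trend(), 1, 1, a))
  expect_equal(ncol(recs[[1]]) - 1, 7)
  expect_setequal(channel_qc(recs), MUSC)
})

test_that("doubling all amplitudes leaves normalized burst matrices unchanged", {
  cfg <- cohort_config(n_subjects = 1, sample_rate = 250, seed = 30)
  trend <- default_trend()
  doubled <- trend
  doubled$table$a <- 2 * doubled$table$a
  doubled$table$b <- 2 * doubled$table$b
  rec1 <- generate_recording(cfg, trend, 1, 1, 20)
  rec2 <- generate_recording(cfg, doubled, 1, 1, 20)
  seg1 <- segment_bursts(rectify(rec1), 6)[[2]]
  seg2 <- segment_bursts(rectify(rec2), 6)[[2]]
  D1 <- normalize_burst(burst_matrix(decimate(lowpass(seg1), 50)))
  D2 <- normalize_burst(burst_matrix(decimate(lowpass(seg2), 50)))
  expect_equal(unclass(D1), unclass(D2), tolerance = 1e-8)
})

test_that("generate_cohort writes per-condition CSVs with a manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 1, positions = 1, angles = c(0, 20),
                       sample_rate = 100, seed = 3)
  out <- generate_cohort(cfg, default_trend(), out_dir = dir)
  files <- list.files(dir)
  expect_true("manifest.json" %in% files)
  expect_length(grep("subject01_pos1_ang", files), 2)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_length(man$recordings, 2)
  # in-memory variant returns the recordings
  mem <- generate_cohort(cfg, default_trend())
  expect_length(mem$recordings, 2)
  expect_equal(nrow(mem$manifest), 2)
})
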