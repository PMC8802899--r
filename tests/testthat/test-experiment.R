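test_that("the default configuration validates cleanly", {
  expect_length(validate_config(experiment_config()), 0)
})

test_that("configuration problems are reported as diagnostics, not errors", {
  cfg <- experiment_config(alpha = 2)
  expect_match(validate_config(cfg), "alpha", all = FALSE)

  net <- build_default_network(n_neurons = 5)
  net$connections$delay[4] <- -2
  cfg2 <- experiment_config(network = net)
  d <- validate_config(cfg2)
  expect_match(d, "connection 4", all = FALSE)
  expect_match(d, "negative delay", all = FALSE)

  net2 <- build_default_network(n_neurons = 5)
  net2$connections$source[2] <- "GhostPop"
  d2 <- validate_config(experiment_config(network = net2))
  expect_match(d2, "unknown source 'GhostPop'", all = FALSE)

  bad_trend <- default_trend()
  bad_trend$table$b <- -bad_trend$table$b
  d3 <- validate_config(experiment_config(trend = bad_trend))
  expect_match(d3, "trend", all = FALSE)
})

test_that("custom afferents build resolvable mechanism schedules", {
  aff <- custom_afferents(senFlInt = 10, senExtInt = 150, senInhRF = 5)
  expect_equal(max(schedule_value(aff$senExtInt, seq(0, 7500, 10))), 150)
  expect_equal(schedule_value(aff$senFlInt, 4000), 10)
  expect_equal(schedule_value(aff$senInhRF, 0), 0)
})

test_that("a reduced experiment is reproducible end to end", {
  cfg <- experiment_config(
    cohort = cohort_config(n_subjects = 2, sample_rate = 250,
                           angles = c(0, 20), seed = 1),
    n_neurons = 30, duration = 7500, seed = 5)
  dir <- withr::local_tempdir()
  r1 <- run_experiment(cfg, out_dir = dir, quiet = TRUE)
  r2 <- run_experiment(cfg, quiet = TRUE)
  expect_identical(r1$means, r2$means)
  expect_identical(r1$model_weights, r2$model_weights)
  expect_identical(r1$checklist, r2$checklist)
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)

  expect_true(all(c("cohort_means.csv", "contrasts.csv", "data_synergies.csv",
                    "model_weights.csv", "checklist.json",
                    "provenance.json") %in% list.files(dir)))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$master_seed, 5)
  expect_equal(prov$correction, "none")
  expect_false(prov$low_n_bursts)

  # the non-normalized variant is produced alongside the normalized one
  expect_equal(nrow(r1$data_synergies), nrow(r1$data_synergies_nonnorm))
  expect_gt(nrow(r1$data_synergies), 0)
})

test_that("single-burst conditions run and are flagged low-n", {
  cfg <- experiment_config(
    cohort = cohort_config(n_subjects = 2, bursts_per_condition = 1,
                           sample_rate = 250, angles = c(0, 20),
                           positions = 1, seed = 2),
    n_neurons = 20, seed = 9)
  res <- run_experiment(cfg, quiet = TRUE)
  expect_true(res$provenance$low_n_bursts)
  expect_gt(nrow(res$contrasts), 0)
})
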