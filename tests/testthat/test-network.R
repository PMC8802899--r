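test_that("the default network reproduces the published connection table", {
  net <- build_default_network(n_neurons = 10)
  expect_length(net$populations, 8)
  cn <- net$connections

  row <- cn[cn$target == "MN-RF" & cn$source == "InhibRF", ]
  expect_equal(row$efficacy, -0.052)
  expect_equal(row$n_connections, 70)
  expect_equal(row$delay, 2)

  # interneuron pools inhibit their namesakes (20) and excite the others (70)
  expect_equal(cn$efficacy[cn$target == "MN-VL" &
                             cn$source == "ExtensorInterneurons"], -0.052)
  expect_equal(cn$n_connections[cn$target == "MN-ST" &
                                  cn$source == "ExtensorInterneurons"], 70)
  expect_equal(cn$efficacy[cn$target == "MN-ST" &
                             cn$source == "ExtensorInterneurons"], 0.052)
  # mutual interneuron inhibition
  expect_equal(cn$efficacy[cn$target == "ExtensorInterneurons" &
                             cn$source == "FlexorInterneurons"], -0.052)
  expect_equal(cn$efficacy[cn$target == "FlexorInterneurons" &
                             cn$source == "ExtensorInterneurons"], -0.052)

  # background drive: 320 Hz into motor pools, 300 Hz into interneuron pools
  input_names <- vapply(net$inputs, function(s) s$name, character(1))
  bg_mn <- net$inputs[[match("BackgroundMN", input_names)]]
  expect_equal(schedule_value(bg_mn, 1000), 320)
  expect_true(any(cn$target == "MN-VL" & cn$source == "BackgroundMN"))
  bg <- net$inputs[[match("Background", input_names)]]
  expect_equal(schedule_value(bg, 1000), 300)
  expect_true(any(cn$target == "InhibRF" & cn$source == "Background"))

  # every external connection: 0.1 mV over 100 connections, no delay
  ext <- cn[!(cn$source %in% vapply(net$populations, `[[`, "", "name")), ]
  expect_true(all(ext$efficacy == 0.1 & ext$n_connections == 100 &
                    ext$delay == 0))
  expect_equal(nrow(cn), 31)  # the full published connection table
  expect_length(validate_network(net), 0)
})

test_that("cortical drive is the documented trapezoid", {
  cd <- make_cortical_drive()
  expect_equal(schedule_value(cd, 4000), 20)            # mid-hold
  expect_equal(schedule_value(cd, 500 + 500), 10)       # half-way up the ramp
  expect_equal(schedule_value(cd, 0), 0)
  expect_equal(schedule_value(cd, 10000), 0)
  zero <- make_cortical_drive(peak = 0)
  expect_true(all(schedule_value(zero, seq(0, 8000, 100)) == 0))
  expect_error(make_cortical_drive(ramp = 0), "ramp")
  expect_error(make_cortical_drive(hold = -1), "negative")
})

test_that("afferent condition presets follow the published schedule", {
  a1 <- make_afferent_condition(1, 20)
  expect_equal(max(schedule_value(a1$senFlInt, seq(0, 7500, 10))), 75)
  expect_equal(max(schedule_value(a1$senInhRF, seq(0, 7500, 10))), 0)

  a2 <- make_afferent_condition(2, 20)
  expect_equal(max(schedule_value(a2$senFlInt, seq(0, 7500, 10))), 38)
  expect_equal(max(schedule_value(a2$senInhRF, seq(0, 7500, 10))), 50)

  # at full extension the two positions are identical
  t <- seq(0, 7500, 10)
  p1 <- make_afferent_condition(1, 0)
  p2 <- make_afferent_condition(2, 0)
  for (nm in names(p1)) {
    expect_equal(schedule_value(p1[[nm]], t), schedule_value(p2[[nm]], t))
  }
  expect_error(make_afferent_condition(1, 45), "unknown")
  expect_error(make_afferent_condition(3, 0), "unknown")
})

test_that("input schedules validate their breakpoints", {
  expect_error(input_schedule("x", c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(input_schedule("x", c(0, 1), c(-1, 2)), "non-negative")
  s <- input_schedule("x", c(0, 100), c(0, 10))
  expect_equal(schedule_value(s, 50), 5)
  expect_equal(schedule_value(s, 200), 10)  # held at the last value
})

test_that("validate_network reports resolution and parameter problems", {
  net <- build_default_network(n_neurons = 5)
  bad <- net
  bad$connections$delay[3] <- -1
  expect_match(validate_network(bad), "negative delay", all = FALSE)
  bad2 <- net
  bad2$connections$target[1] <- "MN-XX"
  expect_match(validate_network(bad2), "unknown target", all = FALSE)
  expect_error(
    network_spec(net$populations,
                 connection("MN-RF", "Nowhere", 0.1, 10, 0), net$inputs),
    "unknown source")
})

test_that("network specs round-trip through YAML and JSON configs", {
  net <- build_default_network(n_neurons = 8, seed = 4)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network_config(net, path)
    back <- read_network_config(path)
    expect_equal(back$connections, net$connections)
    expect_equal(length(back$populations), 8)
    expect_equal(back$populations[[1]]$params, net$populations[[1]]$params)
    expect_equal(back$seed, net$seed)
    t <- seq(0, 7500, 50)
    for (i in seq_along(net$inputs)) {
      expect_equal(schedule_value(back$inputs[[i]], t),
                   schedule_value(net$inputs[[i]], t))
    }
    # and the simulation driven by the round-tripped spec is identical
    expect_identical(as.data.frame(simulate_network(back, 100)),
                     as.data.frame(simulate_network(net, 100)))
  }
})
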