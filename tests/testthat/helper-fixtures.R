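# Shared fixtures and small utilities for the test suite. All fixtures are
# generated in code; simulation sizes are kept small except where a check
# is explicitly about the full-scale behaviour.

# standard error of a plateau-rate estimate from Poisson spike counts:
# rate over a window of `window_s` seconds with `n` neurons
rate_se <- function(rate, n, window_s) {
  sqrt(max(rate, 0.5) / (n * window_s))
}

# mean rates over the cortical-drive hold (default timing: ramp ends at
# 1500 ms, hold ends at 6500 ms; use the central 4 s)
plateau_rates <- function(sim) {
  wr <- window_rates(sim, 2000, 6000)
  setNames(wr$rate, wr$population)
}

# a clean single-burst recording: trapezoid envelope times white noise
make_burst_recording <- function(fs = 500, a = 1, b = 0.1, seed = 1,
                                 channels = c("RF", "VL")) {
  t_ms <- seq(0, 9000 - 1000 / fs, by = 1000 / fs)
  prof <- spinalsynergy:::trapezoid_profile(t_ms, 3000, 500, 5000)
  set.seed(seed)
  rec <- tibble::tibble(time_ms = t_ms)
  for (ch in channels) rec[[ch]] <- (b + a * prof) * rnorm(length(t_ms))
  rec
}

# tidy weight tibble from named synergy-2 weights (for checklist unit tests)
fake_weights <- function(w2, position = 1, angle = 0, run = NULL) {
  out <- tibble::tibble(
    muscle = rep(names(w2), 2),
    synergy = rep(1:2, each = length(w2)),
    weight = c(rep(1, length(w2)), unname(w2)),
    position = position, angle = angle)
  if (!is.null(run)) out$run <- run
  out
}

MUSC <- c("RF", "VL", "VM", "ST", "BF")
EXT <- c("RF", "VL", "VM")
FLEX <- c("ST", "BF")
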