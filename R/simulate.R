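#' Simulate the population network
#'
#' Runs the Monte-Carlo ensemble simulation: each neuron of a target
#' population receives independent Poisson event streams at rate
#' `n_connections` times the (delayed, smoothed) source rate, each event
#' jumping the membrane potential by the connection efficacy; between events
#' the potential follows the EIF drift. Population rates are reported as
#' spike counts per sampling bin divided by ensemble size and bin width.
#' Output is bit-identical for identical specs (including the seed).
#'
#' @param net A `network_spec`.
#' @param duration Simulated time (ms). Must cover all input schedules.
#' @param density_times Optional times (ms) at which to snapshot the ensemble
#'   membrane potentials for [density_snapshot()].
#' @return A tibble with `time_ms` and one rate column (Hz) per population,
#'   carrying the network spec and any density snapshots as attributes.
#' @export
#' @examples
#' net <- build_default_network(n_neurons = 20, seed = 1)
#' sim <- simulate_network(net, duration = 100)
#' head(sim)
simulate_network <- function(net, duration, density_times = NULL) {
  stopifnot(inherits(net, "network_spec"))
  problems <- validate_network(net)
  if (length(problems)) {
    stop_bad("invalid network spec:\n", paste("-", problems, collapse = "\n"))
  }
  dt <- net$dt
  n_steps <- as.integer(round(duration / dt))
  sample_every <- as.integer(round(net$rate_sample_interval / dt))
  if (sample_every < 1) stop_bad("rate_sample_interval must be >= dt")

  pop_names <- vapply(net$populations, function(p) p$name, character(1))
  input_names <- vapply(net$inputs, function(s) s$name, character(1))

  pop_n <- vapply(net$populations, function(p) p$n, integer(1))
  pop_params <- t(vapply(net$populations, function(p) {
    unlist(p$params[c("v_rest", "delta_t", "v_thres", "tau", "v_spike",
                      "v_reset", "t_refractory")])
  }, numeric(7)))

  # external input rates on the step grid
  step_times <- seq(0, n_steps) * dt
  ext_rates <- vapply(net$inputs, schedule_value, numeric(n_steps + 1),
                      t = step_times)
  ext_rates <- matrix(ext_rates, nrow = n_steps + 1)

  # group connections by (target, efficacy): superposed Poisson streams
  cn <- net$connections
  cn$target_idx <- match(cn$target, pop_names) - 1L
  cn$is_ext <- as.integer(!(cn$source %in% pop_names))
  cn$source_idx <- ifelse(cn$is_ext == 1L,
                          match(cn$source, input_names) - 1L,
                          match(cn$source, pop_names) - 1L)
  cn$delay_steps <- as.integer(round(cn$delay / dt))
  key <- paste(cn$target_idx, cn$efficacy)
  groups <- split(seq_len(nrow(cn)), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]

  grp_target <- vapply(groups, function(i) cn$target_idx[i[1]], integer(1))
  grp_eff <- vapply(groups, function(i) cn$efficacy[i[1]], numeric(1))
  grp_src_type <- lapply(groups, function(i) cn$is_ext[i])
  grp_src_idx <- lapply(groups, function(i) cn$source_idx[i])
  grp_nconn <- lapply(groups, function(i) cn$n_connections[i])
  grp_delay <- lapply(groups, function(i) cn$delay_steps[i])

  density_steps <- if (is.null(density_times)) integer(0) else
    as.integer(round(density_times / dt))

  set.seed(net$seed)
  res <- simulate_network_cpp(pop_n, pop_params,
                              as.integer(grp_target), grp_eff,
                              grp_src_type, grp_src_idx, grp_nconn, grp_delay,
                              ext_rates, dt, n_steps, sample_every,
                              net$smooth_tau, density_steps)

  rates <- res$rates
  colnames(rates) <- pop_names
  out <- tibble::as_tibble(as.data.frame(rates, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(time_ms = as.numeric(res$times)), out)

  density <- lapply(res$density, function(snap) {
    pots <- setNames(lapply(snap, as.numeric), pop_names)
    list(time_ms = attr(snap, "step") * dt, potentials = pots)
  })
  attr(out, "network") <- net
  attr(out, "density") <- density
  class(out) <- c("rate_series", class(out))
  out
}

#' Membrane-potential density snapshot
#'
#' Normalized histogram of the ensemble membrane potentials of one
#' population at the snapshot nearest the requested time (snapshots are
#' recorded by passing `density_times` to [simulate_network()]). Neurons in
#' their refractory hold sit at the reset potential and are included, so the
#' mass always sums to one.
#'
#' @param sim Result of [simulate_network()] run with `density_times`.
#' @param population Population name.
#' @param time Requested time (ms).
#' @param bin_width Histogram bin width (mV).
#' @return A tibble with `bin_lo`, `bin_hi`, `bin_mid` (mV) and `mass`.
#' @export
density_snapshot <- function(sim, population, time, bin_width = 0.5) {
  density <- attr(sim, "density")
  if (is.null(density) || !length(density)) {
    stop_bad("no density snapshots recorded; pass `density_times` to simulate_network()")
  }
  times <- vapply(density, function(d) d$time_ms, numeric(1))
  snap <- density[[which.min(abs(times - time))]]
  if (!population %in% names(snap$potentials)) {
    stop_bad("unknown population '", population, "'")
  }
  v <- snap$potentials[[population]]
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width + 1e-9) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
  tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                 bin_mid = (head(edges, -1) + tail(edges, -1)) / 2,
                 mass = counts / length(v),
                 population = population, time_ms = snap$time_ms)
}

#' Mean population rates over a time window
#'
#' Convenience for plateau/baseline measurements: the mean of each
#' population-rate column over `from <= time_ms <= to`.
#'
#' @param sim A rate series from [simulate_network()].
#' @param from,to Window bounds (ms).
#' @return A tibble with `population` and `rate` (Hz).
#' @export
window_rates <- function(sim, from, to) {
  win <- sim[sim$time_ms >= from & sim$time_ms <= to, , drop = FALSE]
  if (!nrow(win)) stop_bad("window contains no samples")
  pops <- setdiff(names(win), "time_ms")
  tibble::tibble(population = pops,
                 rate = vapply(win[pops], mean, numeric(1)))
}
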