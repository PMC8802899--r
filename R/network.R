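#' Declare a neuron population
#'
#' @param name Population name (unique within a network).
#' @param n Ensemble size: number of Monte-Carlo neurons simulated for the
#'   population. The population-density picture is approximated by this
#'   ensemble; 500 reproduces population rates with small sampling error,
#'   smaller ensembles trade precision for speed.
#' @param params [neuron_params()] for every neuron in the population.
#' @return A list of class `population_spec`.
#' @export
population <- function(name, n = 500, params = neuron_params()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is_scalar_num(n) || n < 1) stop_bad("`n` must be >= 1")
  structure(list(name = name, n = as.integer(n), params = params),
            class = "population_spec")
}

#' Declare a connection between populations or from an external input
#'
#' Mirrors the three connection parameters of the circuit description: the
#' instantaneous postsynaptic efficacy (mV jump per incoming spike, signed),
#' the average number of incoming connections per target neuron, and a
#' transmission delay.
#'
#' @param target Target population name.
#' @param source Source population name or external input name.
#' @param efficacy Membrane-potential jump per event (mV, signed, non-zero).
#' @param n_connections Average incoming connections per target neuron (> 0).
#' @param delay Transmission delay (ms, >= 0).
#' @return A one-row tibble.
#' @export
connection <- function(target, source, efficacy, n_connections, delay = 0) {
  if (!is_scalar_num(efficacy) || efficacy == 0) {
    stop_bad("`efficacy` must be a non-zero number")
  }
  if (!is_scalar_num(n_connections) || n_connections <= 0) {
    stop_bad("`n_connections` must be > 0")
  }
  if (!is_scalar_num(delay) || delay < 0) stop_bad("`delay` must be >= 0")
  tibble::tibble(target = target, source = source, efficacy = efficacy,
                 n_connections = n_connections, delay = delay)
}

#' Piecewise-linear external input rate schedule
#'
#' External inputs (background drive, cortical drive, afferents) deliver
#' Poisson spike trains whose rate follows a piecewise-linear profile through
#' the given breakpoints. Outside the breakpoint range the rate is held at
#' the nearest endpoint value.
#'
#' @param name Input name.
#' @param times Breakpoint times (ms), strictly increasing.
#' @param rates Rates at the breakpoints (Hz, >= 0).
#' @return A list of class `input_schedule`.
#' @export
input_schedule <- function(name, times, rates) {
  stopifnot(is.character(name), length(times) == length(rates))
  if (length(times) < 1) stop_bad("need at least one breakpoint")
  if (any(diff(times) <= 0)) stop_bad("breakpoint times must be strictly increasing")
  if (any(rates < 0)) stop_bad("rates must be non-negative")
  structure(list(name = name, times = as.numeric(times),
                 rates = as.numeric(rates)),
            class = "input_schedule")
}

#' Evaluate an input schedule at given times
#'
#' @param schedule An [input_schedule()].
#' @param t Times (ms).
#' @return Rates (Hz) at `t`.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "input_schedule"))
  if (length(schedule$times) == 1L) {
    return(rep(schedule$rates, length(t)))
  }
  approx(schedule$times, schedule$rates, xout = t, rule = 2)$y
}

#' @rdname input_schedule
#' @param rate Constant rate (Hz).
#' @export
constant_schedule <- function(name, rate) {
  input_schedule(name, 0, rate)
}

#' Trapezoidal cortical drive schedule
#'
#' The supraspinal drive responsible for the contraction: 0 Hz at rest,
#' ramping linearly to `peak` over `ramp` ms, held for `hold` ms, then
#' ramping back to 0. Defaults give the 20 Hz drive with 1 s ramps and a 5 s
#' hold used to emulate one contraction burst.
#'
#' @param t_start Time the ramp begins (ms). The default leaves a 500 ms
#'   settling period under background input alone.
#' @param peak Plateau rate (Hz, >= 0).
#' @param ramp Ramp duration (ms, > 0).
#' @param hold Hold duration (ms, >= 0).
#' @param name Input name.
#' @return An [input_schedule()].
#' @export
make_cortical_drive <- function(t_start = 500, peak = 20, ramp = 1000,
                                hold = 5000, name = "CorticalDrive") {
  if (peak < 0) stop_bad("`peak` must be >= 0")
  if (ramp <= 0) stop_bad("`ramp` must be > 0")
  if (hold < 0 || t_start < 0) stop_bad("durations must be non-negative")
  input_schedule(name,
                 times = c(0, t_start, t_start + ramp, t_start + ramp + hold,
                           t_start + 2 * ramp + hold),
                 rates = c(0, 0, peak, peak, 0))
}

#' Afferent plateau rates for each limb position and knee angle
#'
#' The three afferent inputs control the synergy bias: `senFlInt` excites the
#' flexor interneuron pool (net extensor facilitation), `senExtInt` the
#' extensor interneuron pool, and `senInhRF` drives the RF-specific
#' inhibitory population. In position 1 `senFlInt` falls nonlinearly with
#' knee angle (150, 75, 38, 0 Hz); in position 2 it drops immediately from
#' 150 to 38 Hz and `senInhRF` is raised to 50 Hz at the flexed angles.
#' The position-2 value at 60 degrees (19 Hz) continues the halving pattern
#' and is configurable, as is the senInhRF level.
#'
#' @return A tibble with columns `position`, `angle`, `senFlInt`,
#'   `senExtInt`, `senInhRF` (plateau rates, Hz).
#' @export
default_afferent_plateaus <- function() {
  tibble::tribble(
    ~position, ~angle, ~senFlInt, ~senExtInt, ~senInhRF,
    1,   0, 150, 0,  0,
    1,  20,  75, 0,  0,
    1,  60,  38, 0,  0,
    1,  90,   0, 0,  0,
    2,   0, 150, 0,  0,
    2,  20,  38, 0, 50,
    2,  60,  19, 0, 50,
    2,  90,   0, 0, 50
  )
}

#' Afferent input schedules for one experimental condition
#'
#' Builds the three afferent schedules for a (position, angle) condition.
#' Each afferent follows the same trapezoidal envelope as the cortical drive,
#' scaled to its per-condition plateau (afferent activity transitions from
#' 0 Hz to the plateau during the task).
#'
#' @param position Limb position, 1 or 2.
#' @param angle Internal knee angle in degrees: 0, 20, 60 or 90.
#' @param plateaus Plateau table, defaults to [default_afferent_plateaus()].
#' @param t_start,ramp,hold Trapezoid timing (ms), matching the cortical
#'   drive defaults.
#' @return Named list of three [input_schedule()]s: `senFlInt`, `senExtInt`,
#'   `senInhRF`.
#' @export
make_afferent_condition <- function(position, angle,
                                    plateaus = default_afferent_plateaus(),
                                    t_start = 500, ramp = 1000, hold = 5000) {
  row <- plateaus[plateaus$position == position & plateaus$angle == angle, ]
  if (nrow(row) != 1L) {
    stop_bad("unknown position/angle combination: ", position, ", ", angle)
  }
  mk <- function(nm) {
    peak <- row[[nm]]
    if (peak == 0) constant_schedule(nm, 0)
    else make_cortical_drive(t_start, peak, ramp, hold, name = nm)
  }
  setNames(lapply(AFFERENTS, mk), AFFERENTS)
}

#' Assemble a network specification
#'
#' @param populations List of [population()]s.
#' @param connections Tibble of connections (rows from [connection()]).
#' @param inputs List of [input_schedule()]s.
#' @param dt Integration step (ms); 0.1 ms matches the 10 kHz rate generation
#'   of the reference circuit.
#' @param rate_sample_interval Output sampling interval (ms); rates are
#'   reported as spike counts per sampling bin.
#' @param seed RNG seed; identical specs (including seed) give bit-identical
#'   output.
#' @param smooth_tau Time constant (ms) of the exponential smoothing applied
#'   to the per-step population rate before it is delivered to targets;
#'   damps the artificial feedback noise of small ensembles.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(populations, connections, inputs, dt = 0.1,
                         rate_sample_interval = 2, seed = 1L,
                         smooth_tau = 1) {
  net <- structure(list(populations = populations, connections = connections,
                        inputs = inputs, dt = dt,
                        rate_sample_interval = rate_sample_interval,
                        seed = as.integer(seed), smooth_tau = smooth_tau),
                   class = "network_spec")
  problems <- validate_network(net)
  if (length(problems)) {
    stop_bad("invalid network spec:\n", paste("-", problems, collapse = "\n"))
  }
  net
}

#' Validate a network specification
#'
#' Checks that every connection endpoint resolves to a declared population or
#' input, population names are unique, and the numerical settings are sane.
#' Returns diagnostics rather than throwing, so configuration front-ends can
#' report all problems at once.
#'
#' @param net A `network_spec` (or a plain list shaped like one).
#' @return Character vector of problems; empty if valid.
#' @export
validate_network <- function(net) {
  problems <- character()
  pop_names <- vapply(net$populations, function(p) p$name, character(1))
  if (anyDuplicated(pop_names)) {
    problems <- c(problems, "population names must be unique")
  }
  input_names <- vapply(net$inputs, function(s) s$name, character(1))
  cn <- net$connections
  for (i in seq_len(nrow(cn))) {
    if (!(cn$target[i] %in% pop_names)) {
      problems <- c(problems, paste0("connection ", i, ": unknown target '",
                                     cn$target[i], "'"))
    }
    if (!(cn$source[i] %in% c(pop_names, input_names))) {
      problems <- c(problems, paste0("connection ", i, ": unknown source '",
                                     cn$source[i], "'"))
    }
    if (cn$delay[i] < 0) {
      problems <- c(problems, paste0("connection ", i, ": negative delay"))
    }
    if (cn$n_connections[i] <= 0) {
      problems <- c(problems, paste0("connection ", i,
                                     ": n_connections must be > 0"))
    }
  }
  if (!is_scalar_num(net$dt) || net$dt <= 0) {
    problems <- c(problems, "dt must be > 0")
  } else if (net$rate_sample_interval < net$dt) {
    problems <- c(problems, "rate_sample_interval must be >= dt")
  }
  problems
}

#' The default 8-population spinal circuit
#'
#' Builds the spinal network of five motor-neuron pools (MN-RF, MN-VL,
#' MN-VM, MN-ST, MN-BF), mutually inhibiting extensor/flexor interneuron
#' pools, and the RF-specific inhibitory pool InhibRF, with the published
#' connection table: each interneuron pool inhibits its namesake motor pools
#' (-0.052 mV, 20 connections, 2 ms) and excites the opposing pools
#' (+0.052 mV, 70, 2 ms); the interneuron pools inhibit each other
#' (-0.052 mV, 70, 2 ms); InhibRF inhibits MN-RF only (-0.052 mV, 70, 2 ms).
#' Background drive (0.1 mV, 100 connections) runs at 300 Hz into the
#' interneuron/InhibRF pools and 320 Hz into the motor pools; cortical drive
#' and the three afferents connect at 0.1 mV, 100 connections.
#'
#' @param n_neurons Ensemble size per population.
#' @param seed RNG seed for the simulation.
#' @param cortical_drive Cortical drive [input_schedule()].
#' @param afferents Named list of afferent schedules as returned by
#'   [make_afferent_condition()], or `NULL` for all-zero afferents.
#' @param dt,rate_sample_interval See [network_spec()].
#' @param params Neuron parameters shared by all populations.
#' @return A `network_spec`.
#' @export
#' @examples
#' net <- build_default_network(n_neurons = 10)
#' length(net$populations)
build_default_network <- function(n_neurons = 500, seed = 1L,
                                  cortical_drive = make_cortical_drive(),
                                  afferents = NULL,
                                  dt = 0.1, rate_sample_interval = 2,
                                  params = neuron_params()) {
  pops <- lapply(ALL_POPS, population, n = n_neurons, params = params)

  inhib <- -0.052
  excit <- 0.052
  cn <- dplyr::bind_rows(
    # extensor interneurons: inhibit extensor MN pools, excite flexor pools
    purrr::map_dfr(paste0("MN-", EXTENSORS), connection,
                   source = "ExtensorInterneurons", efficacy = inhib,
                   n_connections = 20, delay = 2),
    purrr::map_dfr(paste0("MN-", FLEXORS), connection,
                   source = "ExtensorInterneurons", efficacy = excit,
                   n_connections = 70, delay = 2),
    # flexor interneurons: mirror image
    purrr::map_dfr(paste0("MN-", EXTENSORS), connection,
                   source = "FlexorInterneurons", efficacy = excit,
                   n_connections = 70, delay = 2),
    purrr::map_dfr(paste0("MN-", FLEXORS), connection,
                   source = "FlexorInterneurons", efficacy = inhib,
                   n_connections = 20, delay = 2),
    # RF-specific inhibition
    connection("MN-RF", "InhibRF", inhib, 70, 2),
    # mutual inhibition between the interneuron pools
    connection("ExtensorInterneurons", "FlexorInterneurons", inhib, 70, 2),
    connection("FlexorInterneurons", "ExtensorInterneurons", inhib, 70, 2),
    # background drive: 300 Hz to interneuron-level pools, 320 Hz to MN pools
    purrr::map_dfr(c("ExtensorInterneurons", "FlexorInterneurons", "InhibRF"),
                   connection, source = "Background", efficacy = 0.1,
                   n_connections = 100, delay = 0),
    purrr::map_dfr(MN_POPS, connection, source = "BackgroundMN",
                   efficacy = 0.1, n_connections = 100, delay = 0),
    # cortical drive to all MN pools and both interneuron pools
    purrr::map_dfr(c(MN_POPS, "ExtensorInterneurons", "FlexorInterneurons"),
                   connection, source = "CorticalDrive", efficacy = 0.1,
                   n_connections = 100, delay = 0),
    # afferents
    connection("ExtensorInterneurons", "senExtInt", 0.1, 100, 0),
    connection("FlexorInterneurons", "senFlInt", 0.1, 100, 0),
    connection("InhibRF", "senInhRF", 0.1, 100, 0)
  )

  if (is.null(afferents)) {
    afferents <- setNames(lapply(AFFERENTS, constant_schedule, rate = 0),
                          AFFERENTS)
  }
  inputs <- c(list(constant_schedule("Background", 300),
                   constant_schedule("BackgroundMN", 320),
                   cortical_drive),
              unname(afferents))

  network_spec(pops, cn, inputs, dt = dt,
               rate_sample_interval = rate_sample_interval, seed = seed)
}

#' Replace the afferent schedules of a network
#'
#' @param net A `network_spec`.
#' @param afferents Named list of schedules (names must match existing
#'   inputs).
#' @return The modified `network_spec`.
#' @export
with_afferents <- function(net, afferents) {
  input_names <- vapply(net$inputs, function(s) s$name, character(1))
  for (sch in afferents) {
    idx <- match(sch$name, input_names)
    if (is.na(idx)) stop_bad("no input named '", sch$name, "'")
    net$inputs[[idx]] <- sch
  }
  net
}
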