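#' Exponential integrate-and-fire neuron parameters
#'
#' Bundles the constants of the EIF membrane equation
#' \deqn{\tau \frac{dv}{dt} = -(v - v_{rest}) + \Delta_T
#'   e^{(v - v_{thres})/\Delta_T}}
#' together with the spike/reset conventions used by the simulator. The
#' defaults are the spinal-circuit values: a -70 mV rest, a soft exponential
#' threshold at -56 mV with sharpness 1.48 mV, a 3.3 ms membrane time
#' constant, and a -51 mV spike-detection cutoff. Reset returns the neuron to
#' rest with no refractory period; both are exposed because the population
#' model leaves them free.
#'
#' @param v_rest Resting membrane potential (mV).
#' @param delta_t Exponential sharpness \eqn{\Delta_T} (mV).
#' @param v_thres Soft exponential threshold (mV).
#' @param tau Membrane time constant (ms).
#' @param v_spike Spike-detection cutoff (mV); crossing it emits a spike.
#' @param v_reset Post-spike potential (mV).
#' @param t_refractory Absolute refractory time (ms).
#' @return A list of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' eif_drift(-70, p)
neuron_params <- function(v_rest = -70, delta_t = 1.48, v_thres = -56,
                          tau = 3.3, v_spike = -51, v_reset = -70,
                          t_refractory = 0) {
  for (nm in c("v_rest", "delta_t", "v_thres", "tau", "v_spike", "v_reset",
               "t_refractory")) {
    if (!is_scalar_num(get(nm))) stop_bad("`", nm, "` must be a finite number")
  }
  if (!(v_rest < v_thres && v_thres < v_spike)) {
    stop_bad("need v_rest < v_thres < v_spike")
  }
  if (tau <= 0) stop_bad("`tau` must be positive")
  if (delta_t <= 0) stop_bad("`delta_t` must be positive")
  if (t_refractory < 0) stop_bad("`t_refractory` must be non-negative")
  structure(list(v_rest = v_rest, delta_t = delta_t, v_thres = v_thres,
                 tau = tau, v_spike = v_spike, v_reset = v_reset,
                 t_refractory = t_refractory),
            class = "neuron_params")
}

#' EIF membrane-potential drift
#'
#' Rate of change of the membrane potential between synaptic events, in
#' mV/ms. Below the soft threshold the leak dominates and pulls the neuron
#' back to rest; above it the exponential term takes over and the potential
#' escapes towards the spike cutoff. In the limit `delta_t -> 0` this reduces
#' to the leaky integrate-and-fire drift `-(v - v_rest)/tau`.
#'
#' @param v Membrane potential(s), mV. Vectorized.
#' @param params A [neuron_params()] object.
#' @return Drift in mV/ms, same length as `v`.
#' @export
eif_drift <- function(v, params = neuron_params()) {
  stopifnot(inherits(params, "neuron_params"))
  arg <- pmin((v - params$v_thres) / params$delta_t, 16)
  (-(v - params$v_rest) + params$delta_t * exp(arg)) / params$tau
}
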