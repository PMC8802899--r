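#' Read and write network specifications as YAML/JSON documents
#'
#' Serializes a `network_spec` to a plain configuration document (and back)
#' using the connection-table column names `efficacy_mV`, `n_connections`,
#' `delay_ms` and `rate_hz`, so presets can be edited by hand or generated
#' by other tools. The format chosen follows the file extension: `.yaml` /
#' `.yml` or `.json`.
#'
#' @param net A `network_spec`.
#' @param path Output file (`.yaml`, `.yml` or `.json`).
#' @return `write_network_config()`: `path`, invisibly;
#'   `read_network_config()`: a `network_spec`.
#' @export
write_network_config <- function(net, path) {
  stopifnot(inherits(net, "network_spec"))
  doc <- list(
    dt_ms = net$dt,
    rate_sample_interval_ms = net$rate_sample_interval,
    seed = net$seed,
    smooth_tau_ms = net$smooth_tau,
    populations = lapply(net$populations, function(p) {
      c(list(name = p$name, n = p$n), unclass(p$params))
    }),
    connections = lapply(seq_len(nrow(net$connections)), function(i) {
      r <- net$connections[i, ]
      list(target = r$target, source = r$source,
           efficacy_mV = r$efficacy, n_connections = r$n_connections,
           delay_ms = r$delay)
    }),
    inputs = lapply(net$inputs, function(s) {
      list(name = s$name, time_ms = s$times, rate_hz = s$rates)
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_bad("the 'yaml' package is needed to write YAML configs")
    }
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_bad("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  num <- as.numeric  # JSON readers return integers for whole numbers
  pops <- lapply(doc$populations, function(p) {
    population(p$name, n = p$n,
               params = neuron_params(v_rest = num(p$v_rest),
                                      delta_t = num(p$delta_t),
                                      v_thres = num(p$v_thres),
                                      tau = num(p$tau),
                                      v_spike = num(p$v_spike),
                                      v_reset = num(p$v_reset),
                                      t_refractory = num(p$t_refractory)))
  })
  cn <- purrr::map_dfr(doc$connections, function(r) {
    connection(r$target, r$source, num(r$efficacy_mV),
               num(r$n_connections), num(r$delay_ms))
  })
  inputs <- lapply(doc$inputs, function(s) {
    input_schedule(s$name, num(unlist(s$time_ms)), num(unlist(s$rate_hz)))
  })
  network_spec(pops, cn, inputs, dt = num(doc$dt_ms),
               rate_sample_interval = num(doc$rate_sample_interval_ms),
               seed = doc$seed,
               smooth_tau = num(doc$smooth_tau_ms %||% 1))
}
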