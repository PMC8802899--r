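#' Simulate one experimental condition
#'
#' Builds the default network with the afferent schedules of a (position,
#' angle) condition and runs it for one contraction: 500 ms settling under
#' background input, a 1 s cortical ramp to 20 Hz, a 5 s hold and a 1 s ramp
#' down (7.5 s in total).
#'
#' @param position,angle Condition identifiers.
#' @param n_neurons Ensemble size per population.
#' @param seed Simulation seed.
#' @param duration Simulated time (ms).
#' @param plateaus Afferent plateau table (see
#'   [default_afferent_plateaus()]); override to run ablations.
#' @param ... Passed to [build_default_network()].
#' @return A rate series tibble from [simulate_network()].
#' @export
simulate_condition <- function(position, angle, n_neurons = 500, seed = 1L,
                               duration = 7500,
                               plateaus = default_afferent_plateaus(), ...) {
  aff <- make_afferent_condition(position, angle, plateaus)
  net <- build_default_network(n_neurons = n_neurons, seed = seed,
                               afferents = aff, ...)
  simulate_network(net, duration)
}

#' Build a burst matrix from simulated motor-neuron rates
#'
#' Treats the five motor-pool rate series as one contraction burst and
#' applies the same conditioning as the sEMG pipeline: 4 Hz low-pass
#' smoothing (the Monte-Carlo rate estimates carry shot noise that the
#' underlying population rates do not), decimation, and per-series
#' normalization. Rows are named by muscle (MN- prefix stripped) so data
#' and model decompositions are directly comparable.
#'
#' @param sim A rate series from [simulate_network()].
#' @param cutoff Smoothing cutoff (Hz).
#' @param downsample_to Envelope sampling rate (Hz) for factorization.
#' @param normalize Normalize each series to its maximum.
#' @return A `burst_matrix` (5 x n).
#' @export
rates_to_burst_matrix <- function(sim, cutoff = 4, downsample_to = 50,
                                  normalize = TRUE) {
  rec <- sim[, c("time_ms", MN_POPS)]
  class(rec) <- class(tibble::tibble())
  env <- decimate(lowpass(rec, cutoff = cutoff), to = downsample_to)
  D <- burst_matrix(env)
  rownames(D) <- sub("^MN-", "", rownames(D))
  if (normalize) D <- normalize_burst(D)
  D
}

#' Order synergies by component energy
#'
#' NMF component order is arbitrary; for reporting, synergy 1 is taken as
#' the component with the largest energy \eqn{\|W_j\|^2 \|C_j\|^2} — the
#' coordinated contraction component in this task.
#'
#' @param S A `synergy_decomposition`.
#' @return The decomposition with columns of `W` / rows of `C` reordered.
#' @export
sort_synergies <- function(S) {
  energy <- vapply(seq_len(S$rank), function(j) {
    sum(S$W[, j]^2) * sum(S$C[j, ]^2)
  }, numeric(1))
  ord <- order(energy, decreasing = TRUE)
  S$W <- S$W[, ord, drop = FALSE]
  S$C <- S$C[ord, , drop = FALSE]
  S
}

#' Rank-2 synergy weights from a simulated condition
#'
#' Full model-side pipeline for one simulation: burst matrix, rank-2 NMF,
#' energy ordering, weight normalization, returned tidy.
#'
#' @param sim A rate series from [simulate_network()].
#' @param ... Passed to [rates_to_burst_matrix()].
#' @return Tibble of `muscle`, `synergy`, `weight`, plus the decomposition
#'   as attribute `decomposition`.
#' @export
model_synergy_weights <- function(sim, ...) {
  D <- rates_to_burst_matrix(sim, ...)
  dec <- normalize_synergies(sort_synergies(nmf(D, 2)))
  out <- tidy(dec, "W")
  attr(out, "decomposition") <- dec
  out
}

#' Simulate all condition presets
#'
#' Runs [simulate_condition()] for every row of the plateau table, with
#' per-condition seeds derived from one master seed, and returns the tidy
#' rank-2 synergy weights of each condition.
#'
#' @param plateaus Afferent plateau table.
#' @param n_neurons Ensemble size per population.
#' @param seed Master seed (per-condition seeds are derived from it).
#' @param duration Simulated time per condition (ms).
#' @param keep_sims Also return the raw rate series.
#' @return Tibble of `position`, `angle`, `muscle`, `synergy`, `weight`;
#'   with `keep_sims`, the rate series list rides along as attribute `sims`.
#' @export
simulate_all_conditions <- function(plateaus = default_afferent_plateaus(),
                                    n_neurons = 200, seed = 1L,
                                    duration = 7500, keep_sims = FALSE) {
  sims <- list()
  weights <- purrr::pmap_dfr(
    plateaus[, c("position", "angle")],
    function(position, angle) {
      sim <- simulate_condition(position, angle, n_neurons = n_neurons,
                                seed = derive_seed(seed, "cond", position, angle),
                                duration = duration, plateaus = plateaus)
      if (keep_sims) {
        sims[[paste0("pos", position, "_ang", angle)]] <<- sim
      }
      dplyr::mutate(model_synergy_weights(sim),
                    position = position, angle = angle)
    })
  if (keep_sims) attr(weights, "sims") <- sims
  weights
}
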