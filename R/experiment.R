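#' Afferent schedules from explicit plateau rates
#'
#' Convenience for ablation and mechanism runs outside the eight condition
#' presets (e.g. raising senExtInt above senFlInt, or equal inputs).
#'
#' @param senFlInt,senExtInt,senInhRF Plateau rates (Hz).
#' @param t_start,ramp,hold Trapezoid timing (ms).
#' @return Named list of three [input_schedule()]s.
#' @export
custom_afferents <- function(senFlInt = 0, senExtInt = 0, senInhRF = 0,
                             t_start = 500, ramp = 1000, hold = 5000) {
  plateaus <- tibble::tibble(position = 1, angle = 0,
                             senFlInt = senFlInt, senExtInt = senExtInt,
                             senInhRF = senInhRF)
  make_afferent_condition(1, 0, plateaus, t_start = t_start, ramp = ramp,
                          hold = hold)
}

#' Assemble an experiment configuration
#'
#' One document describing the full in-silico experiment: the synthetic
#' cohort, the trend model, the circuit and its condition presets, the
#' pipeline options and the statistical settings, all seeded from a single
#' master seed (stage seeds are derived with [derive_seed()]).
#'
#' @param cohort A [cohort_config()].
#' @param trend A `trend_model`.
#' @param plateaus Afferent plateau table.
#' @param n_neurons Ensemble size per simulated population.
#' @param duration Simulated time per condition (ms).
#' @param threshold VAF threshold for rank selection.
#' @param nmf_fs Envelope sampling rate for factorization (Hz).
#' @param alpha Significance level.
#' @param seed Master seed.
#' @param network Optional network description to validate/run instead of
#'   the default circuit (a `network_spec` or a compatible list).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              trend = default_trend(),
                              plateaus = default_afferent_plateaus(),
                              n_neurons = 200, duration = 7500,
                              threshold = 0.9, nmf_fs = 50, alpha = 0.05,
                              seed = 1L, network = NULL) {
  structure(list(cohort = cohort, trend = trend, plateaus = plateaus,
                 n_neurons = n_neurons, duration = duration,
                 threshold = threshold, nmf_fs = nmf_fs, alpha = alpha,
                 seed = as.integer(seed), network = network),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Schema and invariant checks on every sub-configuration, returned as
#' diagnostics (never thrown) so front-ends can report all problems at
#' once. An empty result means the configuration is valid.
#'
#' @param cfg An [experiment_config()].
#' @return Character vector of diagnostics.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  ch <- cfg$cohort
  if (!inherits(ch, "cohort_config")) {
    problems <- c(problems, "cohort: not a cohort_config")
  } else {
    if (ch$n_subjects < 1) problems <- c(problems, "cohort: n_subjects must be >= 1")
    if (ch$bursts_per_condition < 1) {
      problems <- c(problems, "cohort: bursts_per_condition must be >= 1")
    }
    if (ch$sample_rate <= 8) {
      problems <- c(problems, "cohort: sample_rate must exceed twice the 4 Hz cutoff")
    }
  }
  trend_problems <- validate_trend(cfg$trend)
  if (length(trend_problems)) {
    problems <- c(problems, paste0("trend: ", trend_problems))
  }
  pl <- cfg$plateaus
  needed <- c("position", "angle", AFFERENTS)
  if (!all(needed %in% names(pl))) {
    problems <- c(problems, "plateaus: missing columns")
  } else if (any(as.matrix(pl[, AFFERENTS]) < 0)) {
    problems <- c(problems, "plateaus: afferent rates must be nonnegative")
  }
  if (cfg$n_neurons < 1) problems <- c(problems, "n_neurons must be >= 1")
  if (cfg$threshold <= 0 || cfg$threshold > 1) {
    problems <- c(problems, "threshold must be in (0, 1]")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha must be in (0, 1)")
  }
  if (!is.null(cfg$network)) {
    net_problems <- validate_network(cfg$network)
    if (length(net_problems)) {
      problems <- c(problems, paste0("network: ", net_problems))
    }
  }
  problems
}

#' Run the full in-silico experiment
#'
#' Orchestrates the complete chain: generate the synthetic cohort and
#' measure its condition amplitudes; extract per-burst data synergies
#' (normalized and non-normalized variants); simulate all condition presets
#' and extract model synergies; run the amplitude and contribution-vector
#' contrasts; evaluate the model-versus-data trend checklist (including the
#' bias-flip and equal-input mechanism runs). All stage seeds derive from
#' the master seed, so a repeated run is identical.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; when given, tidy CSV/JSON reports are
#'   written (`cohort_means.csv`, `contrasts.csv`, `data_synergies.csv`,
#'   `model_weights.csv`, `checklist.json`, `provenance.json`).
#' @param quiet Suppress stage messages.
#' @return List with `means`, `contrasts`, `data_synergies`,
#'   `data_synergies_nonnorm`, `model_weights`, `flip_weights`,
#'   `equal_weights`, `contribution_contrasts`, `checklist`, `provenance`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop_bad("invalid experiment config:\n",
             paste("-", problems, collapse = "\n"))
  }
  say <- function(...) if (!quiet) message("[spinalsynergy] ", ...)

  say("stage 1/5: synthetic cohort amplitudes")
  cohort <- cfg$cohort
  cohort$seed <- derive_seed(cfg$seed, "cohort")
  means <- cohort_condition_means(cohort, cfg$trend)

  say("stage 2/5: data synergies (normalized and non-normalized)")
  data_syn <- extract_cohort_synergies(cohort, cfg$trend,
                                       threshold = cfg$threshold,
                                       nmf_fs = cfg$nmf_fs, normalize = TRUE)
  data_syn_nn <- extract_cohort_synergies(cohort, cfg$trend,
                                          threshold = cfg$threshold,
                                          nmf_fs = cfg$nmf_fs,
                                          normalize = FALSE)

  say("stage 3/5: circuit simulations (8 condition presets + mechanism runs)")
  model_w <- simulate_all_conditions(cfg$plateaus, n_neurons = cfg$n_neurons,
                                     seed = derive_seed(cfg$seed, "model"),
                                     duration = cfg$duration)
  # mechanism runs at the 150 Hz afferent level, where the ensemble resolves
  # the rate differences; three seeds each, averaged by the bias index
  mech_run <- function(label, senFlInt, senExtInt) {
    purrr::map_dfr(1:3, function(r) {
      sim <- simulate_network(
        build_default_network(n_neurons = cfg$n_neurons,
                              seed = derive_seed(cfg$seed, label, r),
                              afferents = custom_afferents(
                                senFlInt = senFlInt, senExtInt = senExtInt)),
        cfg$duration)
      dplyr::mutate(model_synergy_weights(sim), run = r)
    })
  }
  flip_w <- mech_run("flip", senFlInt = 0, senExtInt = 150)
  equal_w <- mech_run("equal", senFlInt = 150, senExtInt = 150)

  say("stage 4/5: statistical contrasts")
  contrasts <- compare_conditions(means, alpha = cfg$alpha)
  subj_w2 <- data_syn |>
    tidyr::unnest_longer("w2", values_to = "weight", indices_to = "muscle") |>
    dplyr::group_by(.data$subject, .data$position, .data$angle, .data$muscle) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop")
  w_contrasts <- contribution_vector_tests(subj_w2, alpha = cfg$alpha)

  say("stage 5/5: trend checklist")
  checklist <- trend_checklist(contrasts, model_w, data_weights = subj_w2,
                               flip_weights = flip_w, equal_weights = equal_w)

  provenance <- list(
    master_seed = cfg$seed,
    stage_seeds = list(cohort = derive_seed(cfg$seed, "cohort"),
                       model = derive_seed(cfg$seed, "model"),
                       flip = derive_seed(cfg$seed, "flip", 1),
                       equal = derive_seed(cfg$seed, "equal", 1)),
    n_neurons = cfg$n_neurons, duration_ms = cfg$duration,
    threshold = cfg$threshold, alpha = cfg$alpha,
    correction = "none",
    low_n_bursts = cohort$bursts_per_condition < 2,
    config_hash = derive_seed(cfg$seed, "hash",
                              paste(deparse(unclass(cohort)), collapse = ""))
  )

  out <- list(means = means, contrasts = contrasts,
              data_synergies = data_syn,
              data_synergies_nonnorm = data_syn_nn,
              model_weights = model_w, flip_weights = flip_w,
              equal_weights = equal_w,
              contribution_contrasts = w_contrasts,
              checklist = checklist, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(means, file.path(out_dir, "cohort_means.csv"), row.names = FALSE)
    write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    syn_flat <- dplyr::select(data_syn, -"w1", -"w2")
    write.csv(syn_flat, file.path(out_dir, "data_synergies.csv"),
              row.names = FALSE)
    write.csv(model_w, file.path(out_dir, "model_weights.csv"),
              row.names = FALSE)
    jsonlite::write_json(checklist, file.path(out_dir, "checklist.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
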