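#' Synthetic cohort configuration
#'
#' Describes the structure of a synthetic sEMG cohort emulating the
#' isometric knee-extension protocol: by default 17 subjects, two limb
#' positions recorded in separate sessions, four internal knee angles
#' (0, 20, 60, 90 degrees) and six ~5 s maximal-effort contraction bursts
#' per condition, sampled at 2 kHz from five muscle channels (optionally
#' plus two noise-only channels emulating the discarded MG/TA recordings).
#'
#' @param n_subjects Number of subjects.
#' @param positions Limb positions included.
#' @param angles Internal knee angles (degrees).
#' @param bursts_per_condition Contractions per condition.
#' @param sample_rate Sampling rate (Hz); must exceed twice the envelope
#'   cutoff used downstream.
#' @param ramp_ms,plateau_ms,gap_ms Burst profile: linear ramp up/down time,
#'   plateau duration, and the rest gap between bursts (all ms).
#' @param noise_sd Standard deviation of the white carrier noise (the
#'   envelope is in the same arbitrary units as the trend amplitudes).
#' @param subject_sd Log-scale SD of the lognormal multiplicative
#'   subject-by-muscle-by-session gain (electrode placement and anatomy
#'   differ per session).
#' @param burst_sd Log-scale SD of the per-burst multiplicative jitter.
#' @param drift_sd Log-scale SD of the slow multiplicative envelope
#'   fluctuation, independent per channel (effort and motor-unit-pool
#'   variation during a maximal contraction; smoothed maximal-effort sEMG
#'   amplitude fluctuates with a CV of roughly 20-30 percent).
#' @param drift_cutoff Bandwidth of the slow fluctuation (Hz).
#' @param include_noise_channels Add `MG` and `TA` noise-only channels.
#' @param seed Cohort master seed; identical configs reproduce the cohort
#'   exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17, positions = c(1, 2),
                          angles = c(0, 20, 60, 90),
                          bursts_per_condition = 6, sample_rate = 2000,
                          ramp_ms = 500, plateau_ms = 5000, gap_ms = 3000,
                          noise_sd = 1, subject_sd = 0.2, burst_sd = 0.05,
                          drift_sd = 0.3, drift_cutoff = 1,
                          include_noise_channels = FALSE, seed = 1L) {
  stopifnot(n_subjects >= 1, bursts_per_condition >= 1, sample_rate > 8)
  structure(list(n_subjects = as.integer(n_subjects), positions = positions,
                 angles = angles,
                 bursts_per_condition = as.integer(bursts_per_condition),
                 sample_rate = sample_rate, ramp_ms = ramp_ms,
                 plateau_ms = plateau_ms, gap_ms = gap_ms,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 burst_sd = burst_sd, drift_sd = drift_sd,
                 drift_cutoff = drift_cutoff,
                 include_noise_channels = include_noise_channels,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default amplitude trend model
#'
#' Plateau amplitude `a` and baseline offset `b` per muscle, angle and
#' position, in arbitrary units (absolute sEMG amplitudes are not comparable
#' across muscles, so only ordinal/ratio structure is meaningful). The table
#' encodes the task's amplitude trends: quadriceps contraction activity
#' falls with increasing knee angle — in position 1 with distinct drops from
#' 0 to 20 and 20 to 60 degrees, in position 2 with a single larger drop at
#' 20 degrees; RF is weaker in position 2 at the flexed angles; ST rises
#' from 0 to 20 degrees in both positions and carries a raised baseline in
#' position 1 at the flexed angles. Each burst envelope is the sum of two
#' latent activation templates,
#' \deqn{env(t) = a \cdot T_1(t) + b \cdot T_2(t), \quad T_1 = s(t), \quad
#'   T_2 = 1 - \kappa\, s(t),}
#' where `s(t)` is the trapezoidal contraction template and `T_2` a
#' baseline template partially suppressed during the contraction
#' (reciprocal inhibition of weakly engaged muscles while the agonists
#' work; `suppression` is the depth \eqn{\kappa}). This is the rank-2
#' latent structure the synergy pipeline is expected to recover: the first
#' synergy is the coordinated contraction, the second the inverse-range
#' baseline feature carried mostly by the antagonists.
#'
#' @return A list of class `trend_model` with `table`, a tibble of
#'   `muscle`, `position`, `angle`, `a`, `b`, and the scalar `suppression`.
#' @export
default_trend <- function() {
  quad1 <- c(1.00, 0.70, 0.46, 0.44)
  quad2 <- c(1.00, 0.48, 0.46, 0.44)
  rf2 <- c(1.00, 0.32, 0.31, 0.30)
  st <- c(0.05, 0.35, 0.35, 0.33)
  bf <- c(0.04, 0.15, 0.15, 0.14)
  angles <- c(0, 20, 60, 90)
  tab <- dplyr::bind_rows(
    tibble::tibble(muscle = "RF", position = 1, angle = angles, a = quad1, b = 0.08),
    tibble::tibble(muscle = "RF", position = 2, angle = angles, a = rf2, b = 0.08),
    tibble::tibble(muscle = "VL", position = 1, angle = angles, a = quad1, b = 0.08),
    tibble::tibble(muscle = "VL", position = 2, angle = angles, a = quad2, b = 0.08),
    tibble::tibble(muscle = "VM", position = 1, angle = angles, a = quad1, b = 0.08),
    tibble::tibble(muscle = "VM", position = 2, angle = angles, a = quad2, b = 0.08),
    tibble::tibble(muscle = "ST", position = 1, angle = angles, a = st,
                   b = c(0.30, 0.45, 0.45, 0.45)),
    tibble::tibble(muscle = "ST", position = 2, angle = angles, a = st, b = 0.30),
    tibble::tibble(muscle = "BF", position = 1, angle = angles, a = bf, b = 0.28),
    tibble::tibble(muscle = "BF", position = 2, angle = angles, a = bf, b = 0.28)
  )
  structure(list(table = tab, suppression = 0.6), class = "trend_model")
}

#' The two latent activation templates of a trend model
#'
#' Ground-truth templates for recovery tests: the contraction template
#' `s(t)` and the baseline template `1 - suppression * s(t)` on the time
#' grid of one burst window.
#'
#' @param trend A `trend_model`.
#' @param t_ms Time grid (ms).
#' @param onset_ms,ramp_ms,plateau_ms Trapezoid timing.
#' @return A 2-row matrix (templates x time).
#' @export
trend_templates <- function(trend, t_ms, onset_ms, ramp_ms, plateau_ms) {
  s <- trapezoid_profile(t_ms, onset_ms, ramp_ms, plateau_ms)
  rbind(contraction = s, baseline = 1 - trend$suppression * s)
}

#' Validate a trend model against its structural invariants
#'
#' @param trend A `trend_model`.
#' @return Character vector of violated invariants; empty if valid.
#' @export
validate_trend <- function(trend) {
  tab <- trend$table
  problems <- character()
  get_a <- function(m, p) {
    rows <- tab[tab$muscle == m & tab$position == p, ]
    rows$a[order(rows$angle)]
  }
  if (any(tab$a < 0) || any(tab$b < 0)) {
    problems <- c(problems, "amplitudes and baselines must be nonnegative")
  }
  supp <- trend$suppression %||% 0
  if (supp < 0 || supp >= 1) {
    problems <- c(problems, "suppression depth must be in [0, 1)")
  }
  for (m in EXTENSORS) {
    for (p in 1:2) {
      if (any(diff(get_a(m, p)) >= 0)) {
        problems <- c(problems,
                      paste0(m, " position ", p,
                             ": quadriceps amplitude must fall strictly with angle"))
      }
    }
    drop1 <- get_a(m, 1)[1] - get_a(m, 1)[2]
    drop2 <- get_a(m, 2)[1] - get_a(m, 2)[2]
    if (drop2 <= drop1) {
      problems <- c(problems,
                    paste0(m, ": position-2 drop from 0 to 20 deg must exceed position 1"))
    }
  }
  rf1 <- get_a("RF", 1); rf2 <- get_a("RF", 2)
  if (any(rf1[2:4] <= rf2[2:4])) {
    problems <- c(problems, "RF must be stronger in position 1 at 20/60/90 deg")
  }
  for (p in 1:2) {
    stp <- get_a("ST", p)
    if (stp[2] <= stp[1]) {
      problems <- c(problems, paste0("ST position ", p,
                                     ": amplitude must rise from 0 to 20 deg"))
    }
  }
  st_b1 <- tab[tab$muscle == "ST" & tab$position == 1, ]
  st_b1 <- st_b1[order(st_b1$angle), ]
  if (any(st_b1$b[2:4] <= st_b1$b[1])) {
    problems <- c(problems, "ST baseline must be raised in position 1 at flexed angles")
  }
  problems
}

# trapezoidal contraction template on [0, 1]
trapezoid_profile <- function(t_ms, onset_ms, ramp_ms, plateau_ms) {
  u <- (t_ms - onset_ms)
  up <- pmin(pmax(u / ramp_ms, 0), 1)
  down <- pmin(pmax((u - ramp_ms - plateau_ms) / ramp_ms, 0), 1)
  up - down
}

# per-(subject, position, muscle) lognormal gains, deterministic in the seed
subject_gains <- function(cfg, subject, position, muscles) {
  set.seed(derive_seed(cfg$seed, "gain", subject, position))
  setNames(rlnorm(length(muscles), 0, cfg$subject_sd), muscles)
}

# slow multiplicative envelope fluctuation, unit mean, independent per call
slow_drift <- function(n, fs, sd, cutoff) {
  if (sd <= 0 || cutoff <= 0) return(rep(1, n))
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99), "low")
  # pad so the filter transient does not bias the start of the recording
  pad <- min(n, ceiling(2 * fs / cutoff))
  d <- as.numeric(signal::filter(bf, rnorm(n + pad)))[(pad + 1):(pad + n)]
  d <- d / sd(d) * sd
  exp(d - sd^2 / 2)
}

#' Generate a single synthetic burst
#'
#' One contraction burst for one muscle and condition: the latent-template
#' envelope `a * s(t) + b * (1 - suppression * s(t))` (see
#' [default_trend()]), optionally modulated by a slow per-channel
#' fluctuation, multiplying zero-mean white Gaussian noise — the standard
#' surrogate for raw (unrectified) sEMG. The returned series spans a
#' pre-burst gap, the burst, and a post-burst gap; its ground truth
#' (onset, `a`, `b`, plateau level) rides along as an attribute.
#'
#' @param trend A `trend_model`.
#' @param muscle Muscle name.
#' @param angle,position Condition.
#' @param cfg A [cohort_config()].
#' @param seed RNG seed for this burst.
#' @return Tibble with `time_ms` and `value`; attribute `truth`.
#' @export
generate_burst <- function(trend, muscle, angle, position,
                           cfg = cohort_config(), seed = 1L) {
  row <- trend$table[trend$table$muscle == muscle &
                       trend$table$position == position &
                       trend$table$angle == angle, ]
  if (nrow(row) != 1L) stop_bad("unknown muscle/angle/position")
  fs <- cfg$sample_rate
  kappa <- trend$suppression %||% 0
  onset <- cfg$gap_ms / 2
  total <- cfg$gap_ms + 2 * cfg$ramp_ms + cfg$plateau_ms
  t_ms <- seq(0, total - 1000 / fs, by = 1000 / fs)
  s <- trapezoid_profile(t_ms, onset, cfg$ramp_ms, cfg$plateau_ms)
  env <- row$a * s + row$b * (1 - kappa * s)
  set.seed(seed)
  env <- env * slow_drift(length(t_ms), fs, cfg$drift_sd, cfg$drift_cutoff)
  value <- env * rnorm(length(t_ms), 0, cfg$noise_sd)
  out <- tibble::tibble(time_ms = t_ms, value = value)
  attr(out, "truth") <- list(onset_ms = onset, a = row$a, b = row$b,
                             plateau = row$a + row$b * (1 - kappa))
  out
}

#' Generate one condition recording (all bursts, all channels)
#'
#' A continuous multichannel series for one (subject, position, angle)
#' condition: a lead-in rest gap followed by `bursts_per_condition` bursts
#' separated by rest gaps, with per-session subject gains and per-burst
#' jitter applied multiplicatively. Optional `MG`/`TA` columns contain
#' unmodulated noise.
#'
#' @param cfg A [cohort_config()].
#' @param trend A `trend_model`.
#' @param subject,position,angle Condition identifiers.
#' @return A recording tibble (`time_ms` + channels); attribute `truth`
#'   holds the burst onsets (ms) and the per-muscle effective `a`, `b`.
#' @export
generate_recording <- function(cfg, trend, subject, position, angle) {
  fs <- cfg$sample_rate
  cycle <- cfg$gap_ms + 2 * cfg$ramp_ms + cfg$plateau_ms
  total <- cfg$gap_ms + cfg$bursts_per_condition * cycle
  t_ms <- seq(0, total - 1000 / fs, by = 1000 / fs)
  n <- length(t_ms)
  onsets <- cfg$gap_ms + (seq_len(cfg$bursts_per_condition) - 1) * cycle

  gains <- subject_gains(cfg, subject, position, MUSCLES)
  set.seed(derive_seed(cfg$seed, "rec", subject, position, angle))
  burst_jitter <- matrix(rlnorm(cfg$bursts_per_condition * length(MUSCLES),
                                0, cfg$burst_sd),
                         nrow = cfg$bursts_per_condition)
  colnames(burst_jitter) <- MUSCLES

  kappa <- trend$suppression %||% 0
  out <- tibble::tibble(time_ms = t_ms)
  truth_amp <- list()
  for (m in MUSCLES) {
    row <- trend$table[trend$table$muscle == m &
                         trend$table$position == position &
                         trend$table$angle == angle, ]
    s <- rep(0, n)
    for (bi in seq_along(onsets)) {
      jit <- burst_jitter[bi, m]
      s <- s + jit * trapezoid_profile(t_ms, onsets[bi], cfg$ramp_ms,
                                       cfg$plateau_ms)
    }
    env <- gains[[m]] * (row$a * s + row$b * (1 - kappa * s))
    env <- pmax(env, 0) * slow_drift(n, fs, cfg$drift_sd, cfg$drift_cutoff)
    out[[m]] <- env * rnorm(n, 0, cfg$noise_sd)
    truth_amp[[m]] <- list(a = row$a * gains[[m]], b = row$b * gains[[m]],
                           plateau = gains[[m]] *
                             (row$a + row$b * (1 - kappa)))
  }
  if (cfg$include_noise_channels) {
    for (m in c("MG", "TA")) {
      out[[m]] <- 0.15 * rnorm(n, 0, cfg$noise_sd)
    }
  }
  attr(out, "truth") <- list(onsets_ms = onsets, amplitudes = truth_amp,
                             subject = subject, position = position,
                             angle = angle)
  out
}

#' Enumerate the cohort's conditions
#'
#' @param cfg A [cohort_config()].
#' @return Tibble of `subject`, `position`, `angle`, one row per recording.
#' @export
cohort_conditions <- function(cfg) {
  tidyr::expand_grid(subject = seq_len(cfg$n_subjects),
                     position = cfg$positions, angle = cfg$angles)
}

#' Apply a function across all cohort recordings
#'
#' Generates each condition recording in turn (never holding the whole
#' cohort in memory) and row-binds `f(recording, meta)` across conditions.
#'
#' @param cfg A [cohort_config()].
#' @param trend A `trend_model`.
#' @param f Function of `(recording, meta)` returning a tibble; `meta` is a
#'   one-row tibble with `subject`, `position`, `angle`.
#' @return The bound results.
#' @export
map_cohort <- function(cfg, trend, f) {
  conds <- cohort_conditions(cfg)
  purrr::pmap_dfr(conds, function(subject, position, angle) {
    rec <- generate_recording(cfg, trend, subject, position, angle)
    meta <- tibble::tibble(subject = subject, position = position,
                           angle = angle)
    f(rec, meta)
  })
}

#' Generate and optionally write the full cohort
#'
#' With `out_dir`, writes one CSV per condition recording plus a
#' `manifest.json` ground-truth sidecar (seeds, conditions, burst onsets,
#' per-muscle amplitudes); without, returns recordings in memory (intended
#' for reduced configurations).
#'
#' @param cfg A [cohort_config()].
#' @param trend A `trend_model` (default [default_trend()]).
#' @param out_dir Output directory, or `NULL` to return recordings.
#' @return Invisibly (with `out_dir`) or visibly a list with `manifest`
#'   (tibble) and, if in memory, `recordings`.
#' @export
generate_cohort <- function(cfg = cohort_config(), trend = default_trend(),
                            out_dir = NULL) {
  problems <- validate_trend(trend)
  if (length(problems)) {
    stop_bad("invalid trend model:\n", paste("-", problems, collapse = "\n"))
  }
  conds <- cohort_conditions(cfg)
  manifest <- list()
  recordings <- if (is.null(out_dir)) vector("list", nrow(conds)) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(conds))) {
    s <- conds$subject[i]; p <- conds$position[i]; a <- conds$angle[i]
    rec <- generate_recording(cfg, trend, s, p, a)
    truth <- attr(rec, "truth")
    entry <- list(subject = s, position = p, angle = a,
                  onsets_ms = truth$onsets_ms, amplitudes = truth$amplitudes)
    if (!is.null(out_dir)) {
      file <- sprintf("subject%02d_pos%d_ang%02d.csv", s, p, a)
      write.csv(rec, file.path(out_dir, file), row.names = FALSE)
      entry$file <- file
    } else {
      recordings[[i]] <- rec
    }
    manifest[[i]] <- entry
  }
  man <- tibble::tibble(subject = conds$subject, position = conds$position,
                        angle = conds$angle,
                        onsets_ms = lapply(manifest, `[[`, "onsets_ms"),
                        amplitudes = lapply(manifest, `[[`, "amplitudes"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(seed = cfg$seed,
                              config = unclass(cfg),
                              recordings = manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(manifest = man, dir = out_dir))
  } else {
    list(manifest = man, recordings = recordings)
  }
}
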