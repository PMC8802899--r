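#' Mean of the central window of a burst
#'
#' The contraction-level summary statistic: the mean over a window (default
#' 4 s) centred on the burst midpoint, covering the bulk of the active
#' phase while excluding the ramps.
#'
#' @param x Numeric vector (one channel of one burst).
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s); must not exceed the burst.
#' @return The window mean.
#' @export
central_window_mean <- function(x, fs, window_s = 4) {
  n <- length(x)
  w <- round(window_s * fs)
  if (w > n) stop_bad("window (", window_s, " s) exceeds the burst length")
  lo <- floor((n - w) / 2) + 1
  mean(x[lo:(lo + w - 1)])
}

#' Central-window means for every channel of a burst segment
#'
#' @param segment A recording segment (rectified, smoothed).
#' @param window_s Window length (s).
#' @return Tibble with `muscle` and `amplitude`.
#' @export
burst_central_means <- function(segment, window_s = 4) {
  fs <- rec_fs(segment)
  chans <- rec_channels(segment)
  tibble::tibble(
    muscle = chans,
    amplitude = vapply(segment[chans], central_window_mean, numeric(1),
                       fs = fs, window_s = window_s)
  )
}

#' Per-subject condition amplitudes for a synthetic cohort
#'
#' Runs the preprocessing chain over every cohort recording — rectify,
#' segment into bursts, smooth each burst at 4 Hz — and summarises each
#' burst by its central-window mean per muscle, averaged over the bursts of
#' the condition (the subject is the unit of observation for the
#' between-condition tests; bursts are averaged within subject).
#'
#' @param cfg A [cohort_config()].
#' @param trend A `trend_model`.
#' @param window_s Central window (s).
#' @param cutoff Envelope cutoff (Hz).
#' @return Tibble of `subject`, `position`, `angle`, `muscle`, `amplitude`.
#' @export
cohort_condition_means <- function(cfg = cohort_config(),
                                   trend = default_trend(),
                                   window_s = 4, cutoff = 4) {
  map_cohort(cfg, trend, function(rec, meta) {
    rec <- rectify(rec[, c("time_ms", MUSCLES)])
    segs <- segment_bursts(rec, expected = cfg$bursts_per_condition)
    per_burst <- purrr::map_dfr(segs, function(s) {
      burst_central_means(lowpass(s, cutoff = cutoff), window_s = window_s)
    })
    per_burst |>
      dplyr::group_by(.data$muscle) |>
      dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop") |>
      dplyr::mutate(subject = meta$subject, position = meta$position,
                    angle = meta$angle)
  })
}

#' Per-burst synergy extraction for a synthetic cohort
#'
#' For each burst of each cohort recording: smooth at 4 Hz, decimate,
#' normalize each muscle series to its maximum, select the NMF rank by the
#' VAF rule, and keep the rank-2 contribution vectors (components ordered by
#' energy, weights normalized to max 1).
#'
#' @param cfg A [cohort_config()].
#' @param trend A `trend_model`.
#' @param threshold VAF threshold for rank selection.
#' @param nmf_fs Envelope sampling rate (Hz) used for factorization.
#' @param normalize Normalize each burst series to its maximum first.
#' @return Tibble with one row per burst: condition identifiers,
#'   `selected_rank`, `discarded`, `vaf_rank2`, and `w2` / `w1` list-columns
#'   of named weight vectors.
#' @export
extract_cohort_synergies <- function(cfg = cohort_config(),
                                     trend = default_trend(),
                                     threshold = 0.9, nmf_fs = 50,
                                     normalize = TRUE) {
  map_cohort(cfg, trend, function(rec, meta) {
    rec <- rectify(rec[, c("time_ms", MUSCLES)])
    segs <- segment_bursts(rec, expected = cfg$bursts_per_condition)
    purrr::imap_dfr(segs, function(s, bi) {
      env <- decimate(lowpass(s, cutoff = 4), to = nmf_fs)
      D <- burst_matrix(env)
      if (normalize) D <- normalize_burst(D)
      sel <- select_rank(D, threshold = threshold)
      dec2 <- if (sel$rank == 2) sel$decomposition else nmf(D, 2)
      dec2 <- normalize_synergies(sort_synergies(dec2))
      tibble::tibble(subject = meta$subject, position = meta$position,
                     angle = meta$angle, burst = bi,
                     selected_rank = sel$rank, discarded = sel$discarded,
                     vaf_rank2 = dec2$vaf_global,
                     w1 = list(dec2$W[, 1]), w2 = list(dec2$W[, 2]))
    })
  })
}

safe_welch <- function(x, y, var_equal = FALSE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p_value = 1))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

pairwise_contrasts <- function(df, value, alpha, var_equal) {
  df$.value <- df[[value]]
  angles <- sort(unique(df$angle))
  positions <- sort(unique(df$position))
  out <- list()

  # adjacent-angle contrasts within position
  for (m in unique(df$muscle)) {
    for (p in positions) {
      for (i in seq_len(length(angles) - 1)) {
        a1 <- angles[i]; a2 <- angles[i + 1]
        x <- df$.value[df$muscle == m & df$position == p & df$angle == a1]
        y <- df$.value[df$muscle == m & df$position == p & df$angle == a2]
        if (length(x) < 2 || length(y) < 2) next
        tt <- safe_welch(x, y, var_equal)
        out[[length(out) + 1]] <- tibble::tibble(
          muscle = m, contrast = "angle", position = p,
          group1 = as.character(a1), group2 = as.character(a2),
          mean1 = mean(x), mean2 = mean(y),
          statistic = tt$statistic, p_value = tt$p_value)
      }
    }
  }
  # position contrasts within angle
  if (length(positions) == 2) {
    for (m in unique(df$muscle)) {
      for (a in angles) {
        x <- df$.value[df$muscle == m & df$position == positions[1] &
                         df$angle == a]
        y <- df$.value[df$muscle == m & df$position == positions[2] &
                         df$angle == a]
        if (length(x) < 2 || length(y) < 2) next
        tt <- safe_welch(x, y, var_equal)
        out[[length(out) + 1]] <- tibble::tibble(
          muscle = m, contrast = "position", position = NA_real_,
          group1 = paste0("pos", positions[1], "@", a),
          group2 = paste0("pos", positions[2], "@", a),
          mean1 = mean(x), mean2 = mean(y),
          statistic = tt$statistic, p_value = tt$p_value)
      }
    }
  }
  if (!length(out)) {
    # degenerate groups (single observations): a typed empty table
    out <- list(tibble::tibble(
      muscle = character(), contrast = character(), position = numeric(),
      group1 = character(), group2 = character(),
      mean1 = numeric(), mean2 = numeric(),
      statistic = numeric(), p_value = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res$significant <- res$p_value < alpha
  res
}

#' Between-condition amplitude contrasts
#'
#' Two-sided Welch t tests (pooled-variance optional) per muscle: adjacent
#' knee angles within each position, and position 1 versus position 2 within
#' each angle. No multiple-testing correction is applied, matching the
#' original reporting; the output metadata records this.
#'
#' @param means Tibble with `subject`, `position`, `angle`, `muscle` and the
#'   value column.
#' @param value Name of the value column.
#' @param alpha Significance level.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Tibble of contrasts with `statistic`, `p_value`, `significant`;
#'   attribute `correction = "none"`.
#' @export
compare_conditions <- function(means, value = "amplitude", alpha = 0.05,
                               var_equal = FALSE) {
  res <- pairwise_contrasts(means, value, alpha, var_equal)
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- "none"
  res
}

#' Contrasts on synergy contribution-vector components
#'
#' The same two-sided test structure as [compare_conditions()], applied to
#' per-subject muscle contribution weights (by default the second synergy,
#' where the angle and position trends live).
#'
#' @param weights Tibble with `subject`, `position`, `angle`, `muscle`,
#'   `weight` (one row per subject-condition-muscle).
#' @param alpha Significance level.
#' @param var_equal Use the pooled-variance t test.
#' @return Tibble of contrasts.
#' @export
contribution_vector_tests <- function(weights, alpha = 0.05,
                                      var_equal = FALSE) {
  res <- pairwise_contrasts(weights, "weight", alpha, var_equal)
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- "none"
  res
}

checklist_contrast <- function(contrasts, m, p, a1, a2, direction) {
  row <- contrasts[contrasts$muscle == m & contrasts$contrast == "angle" &
                     !is.na(contrasts$position) & contrasts$position == p &
                     contrasts$group1 == as.character(a1) &
                     contrasts$group2 == as.character(a2), ]
  if (nrow(row) != 1) return(NA)
  row$significant & sign(row$mean2 - row$mean1) == direction
}

checklist_position <- function(contrasts, m, a) {
  row <- contrasts[contrasts$muscle == m & contrasts$contrast == "position" &
                     contrasts$group1 == paste0("pos1@", a), ]
  if (nrow(row) != 1) return(NA)
  row$significant & row$mean1 > row$mean2
}

#' Synergy-2 flexor-versus-extensor bias index
#'
#' The mechanism summary used throughout the model-side checks:
#' \eqn{\beta = \max_m(W_{2,flexors}) - \max_m(W_{2,extensors})} on
#' max-normalized weights, in `[-1, 1]`. The second synergy loads the
#' low-activity muscle group, so \eqn{\beta > 0} is the antagonist
#' (flexor) bias seen when senFlInt dominates, \eqn{\beta < 0} the flipped
#' agonist bias when senExtInt dominates, and \eqn{\beta \approx 0} (over
#' repeated runs) the cancelled trend under equal inputs. The group maximum
#' (not the mean) is used because sampling noise concentrates the
#' component's loading on one channel of the low-activity group.
#'
#' @param weights Tidy weights (`muscle`, `synergy`, `weight`), possibly
#'   several runs; `beta` is averaged over runs if a `run` column exists.
#' @return The bias index (scalar).
#' @export
synergy_bias <- function(weights) {
  w2 <- weights[weights$synergy == 2, ]
  per_run <- if ("run" %in% names(w2)) split(w2, w2$run) else list(w2)
  mean(vapply(per_run, function(w) {
    max(w$weight[w$muscle %in% FLEXORS]) -
      max(w$weight[w$muscle %in% EXTENSORS])
  }, numeric(1)))
}

w2_means <- function(weights, pos, ang) {
  w <- weights[weights$synergy == 2 & weights$position == pos &
                 weights$angle == ang, ]
  tapply(w$weight, w$muscle, mean)
}

#' Model-versus-data trend checklist
#'
#' Evaluates the qualitative claims that tie the simulated circuit to the
#' recorded data, each from computed quantities: the quadriceps amplitude
#' drops (0-20 deg in both positions; 20-60 deg in position 1 only), the ST
#' rise from 0 to 20 deg, RF stronger in position 1 at the flexed angles,
#' the antagonist bias of the model's second synergy at 0 deg, the
#' flattening of the data-side synergy-2 contrast towards 90 deg (the
#' quadriceps components rise with angle while ST falls; a data-side claim —
#' the circuit's extensor weights stay near zero instead), the bias flip
#' when senExtInt exceeds senFlInt, and the
#' elimination of the synergy-2 trend when the two interneuron afferents
#' are equal.
#'
#' @param data_contrasts Output of [compare_conditions()] on cohort
#'   amplitudes.
#' @param model_weights Tidy synergy weights for the eight condition presets:
#'   `position`, `angle`, `muscle`, `synergy`, `weight` (normalized).
#' @param data_weights Per-subject synergy-2 weights from the cohort
#'   (`subject`, `position`, `angle`, `muscle`, `weight`), for the
#'   flattening item (optional).
#' @param flip_weights Tidy weights from run(s) with senExtInt above
#'   senFlInt (optional; a `run` column averages several runs).
#' @param equal_weights Tidy weights from run(s) with equal afferents
#'   (optional).
#' @param bias_margin Minimum |bias index| that counts as a directional
#'   bias.
#' @param cancel_margin Bound on the |bias index| under which the trend
#'   counts as cancelled.
#' @return Tibble with `item` and logical `pass` (NA where the needed input
#'   was not supplied).
#' @export
trend_checklist <- function(data_contrasts, model_weights,
                            data_weights = NULL,
                            flip_weights = NULL, equal_weights = NULL,
                            bias_margin = 0.5, cancel_margin = 0.45) {
  quad_drop_0_20 <- all(vapply(EXTENSORS, function(m) {
    all(vapply(1:2, function(p)
      isTRUE(checklist_contrast(data_contrasts, m, p, 0, 20, -1)), logical(1)))
  }, logical(1)))
  quad_drop_20_60_pos1 <- all(vapply(EXTENSORS, function(m) {
    isTRUE(checklist_contrast(data_contrasts, m, 1, 20, 60, -1))
  }, logical(1)))
  st_rise <- all(vapply(1:2, function(p)
    isTRUE(checklist_contrast(data_contrasts, "ST", p, 0, 20, 1)), logical(1)))
  rf_pos1 <- all(vapply(c(20, 60, 90), function(a)
    isTRUE(checklist_position(data_contrasts, "RF", a)), logical(1)))

  m0 <- model_weights[model_weights$position == 1 & model_weights$angle == 0, ]
  antagonist_bias_0 <- synergy_bias(m0) > bias_margin

  # flattening of the data-side synergy-2 contrast between antagonists and
  # agonists: the quadriceps components rise with angle while ST falls from
  # its extreme value at full extension
  flattening <- if (is.null(data_weights)) NA else {
    dw <- data_weights
    dw$synergy <- 2
    w0 <- w2_means(dw, 1, 0)
    w90 <- w2_means(dw, 1, 90)
    mean(w90[EXTENSORS]) > mean(w0[EXTENSORS]) && w90["ST"] < w0["ST"]
  }
  bias_flip <- if (is.null(flip_weights)) NA else {
    synergy_bias(flip_weights) < -bias_margin
  }
  cancellation <- if (is.null(equal_weights)) NA else {
    abs(synergy_bias(equal_weights)) < cancel_margin
  }

  tibble::tibble(
    item = c("quad-drop-0-20", "quad-drop-20-60-pos1", "st-rise-0-20",
             "rf-pos1-greater", "synergy2-antagonist-bias-at-0",
             "synergy2-flattening-with-angle", "bias-flip-under-senExtInt",
             "equal-input-cancellation"),
    pass = c(quad_drop_0_20, quad_drop_20_60_pos1, st_rise, rf_pos1,
             antagonist_bias_0, flattening, bias_flip, cancellation)
  )
}
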