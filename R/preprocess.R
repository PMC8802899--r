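#' Recording helpers
#'
#' A recording is a tibble whose first column is `time_ms` (uniformly
#' sampled) and whose remaining columns are signal channels. This is the
#' dialect written by the simulator (`time_ms`, `MN-RF`, ...) and by the
#' synthetic cohort generator (`time_ms`, `RF`, `VL`, ...).
#'
#' @param rec A recording tibble.
#' @return `rec_channels()`: channel names; `rec_fs()`: sampling rate (Hz).
#' @export
rec_channels <- function(rec) setdiff(names(rec), "time_ms")

#' @rdname rec_channels
#' @export
rec_fs <- function(rec) {
  dt <- diff(rec$time_ms[1:2])
  1000 / dt
}

#' Full-wave rectification
#'
#' Elementwise absolute value of every channel; the first preprocessing step
#' for raw sEMG-like signals.
#'
#' @param rec A recording.
#' @return The rectified recording.
#' @export
rectify <- function(rec) {
  dplyr::mutate(rec, dplyr::across(-"time_ms", abs))
}

#' Butterworth low-pass filtering
#'
#' Applies a low-pass Butterworth filter to every channel. The default (4 Hz,
#' second order, single-pass causal) produces the smooth envelope used for
#' synergy extraction, deliberately discarding granular activation detail so
#' that the factorization captures maximal and baseline activity. Set
#' `zero_phase = TRUE` for forward-backward filtering when phase lag matters.
#'
#' @param rec A recording.
#' @param cutoff Cutoff frequency (Hz); must be below the Nyquist frequency.
#' @param order Filter order.
#' @param zero_phase Use `signal::filtfilt()` instead of a causal pass.
#' @return The filtered recording.
#' @export
lowpass <- function(rec, cutoff = 4, order = 2, zero_phase = FALSE) {
  fs <- rec_fs(rec)
  if (cutoff >= fs / 2) {
    stop_bad("`cutoff` (", cutoff, " Hz) must be below the Nyquist frequency (",
             fs / 2, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  f <- if (zero_phase) {
    function(x) as.numeric(signal::filtfilt(bf, x))
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  dplyr::mutate(rec, dplyr::across(-"time_ms", f))
}

#' Decimate a low-passed recording
#'
#' Keeps every `factor`-th sample. Intended for envelopes already low-pass
#' filtered well below the new Nyquist frequency (a 4 Hz envelope loses
#' nothing at 100 Hz), which keeps the factorization matrices small.
#'
#' @param rec A recording.
#' @param to Target sampling rate (Hz).
#' @return The decimated recording.
#' @export
decimate <- function(rec, to = 100) {
  fs <- rec_fs(rec)
  factor <- max(1L, as.integer(round(fs / to)))
  rec[seq(1, nrow(rec), by = factor), , drop = FALSE]
}

#' Channel quality control by signal-to-noise ratio
#'
#' Retains channels whose burst-to-baseline amplitude ratio reaches
#' `snr_threshold` in at least one supplied recording. The ratio is the 90th
#' over the 10th percentile of the channel's rectified, smoothed envelope:
#' near-noise channels (no task modulation anywhere, like the discarded MG
#' and TA recordings) sit close to 1, active channels well above it. Passing
#' several recordings (e.g. all conditions of a session) reproduces the
#' cohort-level discard rule, since a muscle may be quiescent in some
#' conditions yet clearly active in others.
#'
#' @param rec A recording or a list of recordings (raw or rectified).
#' @param snr_threshold Minimum burst/baseline ratio; 0 retains everything.
#' @param cutoff Envelope smoothing cutoff (Hz).
#' @return Character vector of retained channel names.
#' @export
channel_qc <- function(rec, snr_threshold = 2, cutoff = 4) {
  recs <- if (is.data.frame(rec)) list(rec) else rec
  chans <- rec_channels(recs[[1]])
  ratio <- setNames(rep(0, length(chans)), chans)
  for (r in recs) {
    env <- lowpass(rectify(r), cutoff = cutoff)
    for (ch in chans) {
      x <- env[[ch]]
      q <- quantile(x, c(0.1, 0.9), names = FALSE)
      rr <- if (q[1] <= 0) Inf else q[2] / q[1]
      ratio[ch] <- max(ratio[ch], rr)
    }
  }
  keep <- chans[ratio >= snr_threshold]
  if (length(keep) < 2) {
    stop_bad("fewer than 2 channels retained by channel QC")
  }
  keep
}

#' Segment a recording into equal-length burst windows
#'
#' Automates the burst segmentation of a multi-burst contraction recording
#' with a dual-threshold (hysteresis) detector on the reference channel's
#' rectified 4 Hz envelope: candidate bursts are contiguous runs above a
#' high threshold (baseline plus `onset_fraction` of the envelope range,
#' robust against baseline noise bumps), merged across gaps shorter than
#' `min_gap_ms`; the onset is then refined by walking back from each run to
#' the last crossing of the low threshold (baseline mean plus `k` baseline
#' standard deviations). Equal-length windows (the median inter-burst
#' interval, or 1.5 times the burst extent for a single burst) are centred
#' on each burst and clipped to the recording.
#'
#' @param rec A rectified recording.
#' @param expected Number of bursts that must be found; a mismatch is an
#'   error.
#' @param reference Reference channel for onset detection; by default the
#'   channel with the strongest relative envelope modulation (90th over
#'   10th percentile), which keeps detection robust when the feedback
#'   muscle is weakly engaged in a condition.
#' @param k Low (onset) threshold in baseline standard deviations.
#' @param onset_fraction High (detection) threshold as a fraction of the
#'   baseline-to-peak envelope range.
#' @param min_gap_ms Supra-threshold runs closer than this are merged.
#' @param min_duration_ms Runs shorter than this are discarded as noise.
#' @return A list of `expected` recordings (segments); each carries the
#'   detected `onset_ms` and `center_ms` as attributes.
#' @export
segment_bursts <- function(rec, expected, reference = NULL, k = 3,
                           onset_fraction = 0.4,
                           min_gap_ms = 1500, min_duration_ms = 500) {
  fs <- rec_fs(rec)
  if (is.null(reference)) {
    envs <- lowpass(rectify(rec), cutoff = 4)
    # strongest relative burst modulation wins; an absolute range would be
    # fooled by slow drift on a high-baseline, weakly modulated channel
    ratios <- vapply(rec_channels(rec), function(ch) {
      q <- quantile(envs[[ch]], c(0.1, 0.9), names = FALSE)
      if (q[1] <= 0) Inf else q[2] / q[1]
    }, numeric(1))
    reference <- names(which.max(ratios))
    env <- envs[[reference]]
  } else {
    env <- lowpass(rectify(rec[, c("time_ms", reference)]),
                   cutoff = 4)[[reference]]
  }

  baseline <- env[env <= quantile(env, 0.3, names = FALSE)]
  base_mean <- mean(baseline)
  thr_low <- base_mean + k * sd(baseline)
  peak <- quantile(env, 0.98, names = FALSE)
  thr_high <- base_mean + onset_fraction * (peak - base_mean)
  thr_high <- max(thr_high, thr_low)
  above <- env > thr_high & is.finite(env)
  if (!any(above) || thr_high <= 0) {
    stop_bad("no bursts detected (flat or sub-threshold signal)")
  }

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- data.frame(start = starts[runs$values], end = ends[runs$values])
  # merge runs separated by short gaps
  min_gap <- min_gap_ms * fs / 1000
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$start[i] - merged$end[nrow(merged)] < min_gap) {
      merged$end[nrow(merged)] <- seg$end[i]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  min_dur <- min_duration_ms * fs / 1000
  merged <- merged[(merged$end - merged$start) >= min_dur, , drop = FALSE]
  # a deep envelope dip can split one burst in two; the two halves are far
  # closer together than any true inter-burst gap, so merge a pair only when
  # its separation is clearly below the typical one
  while (nrow(merged) > expected) {
    gaps <- merged$start[-1] - merged$end[-nrow(merged)]
    i <- which.min(gaps)
    if (gaps[i] >= 0.75 * median(gaps)) break
    merged$end[i] <- merged$end[i + 1]
    merged <- merged[-(i + 1), , drop = FALSE]
  }
  if (nrow(merged) != expected) {
    stop_bad("detected ", nrow(merged), " bursts but expected ", expected)
  }

  # onset refinement: walk back to the last sub-low-threshold sample
  merged$onset <- vapply(merged$start, function(st) {
    below <- which(env[seq_len(st)] <= thr_low)
    if (length(below)) max(below) + 1L else 1L
  }, integer(1))

  centers <- round((merged$start + merged$end) / 2)
  if (nrow(merged) >= 2) {
    win <- round(median(diff(centers)))
  } else {
    win <- round(1.5 * (merged$end - merged$start + 1))
  }
  win <- min(win, nrow(rec))
  half <- win %/% 2

  out <- vector("list", nrow(merged))
  for (i in seq_along(centers)) {
    lo <- centers[i] - half
    lo <- max(1, min(lo, nrow(rec) - win + 1))
    segment <- rec[lo:(lo + win - 1), , drop = FALSE]
    attr(segment, "onset_ms") <- rec$time_ms[merged$onset[i]]
    attr(segment, "center_ms") <- rec$time_ms[centers[i]]
    attr(segment, "burst") <- i
    out[[i]] <- segment
  }
  out
}

#' Build a burst matrix from a segmented recording
#'
#' Stacks the channels of one burst segment into the nonnegative matrix `D`
#' (channels x time) on which the factorization operates.
#'
#' @param segment A recording segment (rectified, usually smoothed).
#' @param channels Channels to include, in row order (default: all).
#' @return A numeric matrix with one row per channel, class `burst_matrix`.
#' @export
burst_matrix <- function(segment, channels = NULL) {
  channels <- channels %||% rec_channels(segment)
  D <- t(as.matrix(segment[, channels, drop = FALSE]))
  D[D < 0] <- 0
  rownames(D) <- channels
  structure(D, class = c("burst_matrix", class(D)),
            normalized = FALSE,
            fs = rec_fs(segment))
}

#' Normalize each burst series to its maximum
#'
#' Divides each row (muscle) of a burst matrix by its maximum, so every
#' series peaks at 1; all-zero rows are left at zero. Normalization moves
#' cross-muscle amplitude differences (which are not comparable in sEMG)
#' out of the first synergy and into the second.
#'
#' @param D A `burst_matrix` (or plain nonnegative matrix).
#' @return The normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_burst <- function(D) {
  if (any(D < 0)) stop_bad("burst matrix must be nonnegative")
  mx <- apply(D, 1, max)
  scale <- ifelse(mx > 0, mx, 1)
  out <- D / scale
  attributes(out) <- attributes(D)
  attr(out, "normalized") <- TRUE
  out
}
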