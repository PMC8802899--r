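#' Plot a synergy decomposition
#'
#' Bar charts of the muscle contribution vectors and line plots of the
#' activation patterns, one facet per synergy — the standard presentation of
#' an NMF muscle-synergy result.
#'
#' @param object A `synergy_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_decomposition <- function(object, ...) {
  w <- tidy(object, "W")
  w$muscle <- factor(w$muscle, levels = object$muscles)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~synergy, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "contribution weight") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.synergy_decomposition
#' @export
plot_activation_patterns <- function(object, ...) {
  cc <- tidy(object, "C")
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$sample, y = .data$activation,
                                   colour = factor(.data$synergy))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample", y = "activation", colour = "synergy") +
    ggplot2::theme_minimal()
}

#' VAF scree plot for rank selection
#'
#' @param object A `rank_selection`.
#' @param ... Unused.
#' @return A ggplot object showing global VAF against rank with the
#'   selection threshold.
#' @export
autoplot.rank_selection <- function(object, ...) {
  ggplot2::ggplot(object$per_rank,
                  ggplot2::aes(x = .data$rank, y = .data$vaf_global)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "rank", y = "global VAF") +
    ggplot2::theme_minimal()
}

#' Plot simulated population rate series
#'
#' @param sim A rate series from [simulate_network()].
#' @param populations Which populations to show (default: the motor pools).
#' @return A ggplot object.
#' @export
plot_rate_series <- function(sim, populations = NULL) {
  populations <- populations %||% intersect(MN_POPS, names(sim))
  long <- tidyr::pivot_longer(sim[, c("time_ms", populations)],
                              -"time_ms", names_to = "population",
                              values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms / 1000, y = .data$rate,
                                     colour = .data$population)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "population rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot cohort condition means
#'
#' Mean central-window amplitude per muscle, angle and position — the
#' summary view of the synthetic cohort's amplitude trends.
#'
#' @param means Tibble with columns `muscle`, `position`, `angle`,
#'   `amplitude` (e.g. from [cohort_condition_means()]).
#' @return A ggplot object.
#' @export
plot_condition_means <- function(means) {
  df <- means |>
    dplyr::group_by(.data$muscle, .data$position, .data$angle) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  df$muscle <- factor(df$muscle, levels = MUSCLES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$amplitude,
                                   colour = factor(.data$position))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "internal knee angle (deg)", y = "amplitude (a.u.)",
                  colour = "position") +
    ggplot2::theme_minimal()
}
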