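#' Tidy a synergy decomposition
#'
#' @param x A `synergy_decomposition`.
#' @param matrix Which factor to tidy: `"W"` (muscle contribution vectors,
#'   default) or `"C"` (activation patterns).
#' @param ... Unused.
#' @return A tibble in long form: for `"W"`, columns `muscle`, `synergy`,
#'   `weight`; for `"C"`, columns `synergy`, `sample`, `activation`.
#' @export
tidy.synergy_decomposition <- function(x, matrix = c("W", "C"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      muscle = rep(x$muscles, times = x$rank),
      synergy = rep(seq_len(x$rank), each = length(x$muscles)),
      weight = as.numeric(x$W)
    )
  } else {
    tibble::tibble(
      synergy = rep(seq_len(x$rank), times = ncol(x$C)),
      sample = rep(seq_len(ncol(x$C)), each = x$rank),
      activation = as.numeric(x$C)
    )
  }
}

#' One-row summary of a synergy decomposition
#'
#' @param x A `synergy_decomposition`.
#' @param ... Unused.
#' @return A tibble with `rank`, `vaf_global`, the minimum per-muscle VAF,
#'   `converged` and `iterations`.
#' @export
glance.synergy_decomposition <- function(x, ...) {
  tibble::tibble(rank = x$rank,
                 vaf_global = x$vaf_global,
                 vaf_min_muscle = min(x$vaf_per_muscle),
                 converged = x$converged,
                 iterations = x$iterations)
}

#' @export
tidy.rank_selection <- function(x, ...) x$per_rank

#' @export
glance.rank_selection <- function(x, ...) {
  tibble::tibble(rank = x$rank, discarded = x$discarded,
                 threshold = x$threshold,
                 vaf_global = x$decomposition$vaf_global)
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat("<synergy_decomposition> rank", x$rank,
      sprintf("| global VAF %.1f%%", 100 * x$vaf_global),
      if (isTRUE(x$normalized)) "| normalized" else "", "\n")
  invisible(x)
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("<rank_selection>", x$rank, "synergies",
      if (x$discarded) "(discarded: VAF below threshold)" else "", "\n")
  invisible(x)
}
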