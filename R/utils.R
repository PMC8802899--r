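#' Derive a reproducible child seed from a master seed
#'
#' Stages of the experiment (cohort generation, each simulated condition,
#' permutation tests) draw their own seeds deterministically from one master
#' seed plus a label, so any stage can be re-run in isolation and the whole
#' experiment is reproducible end to end.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the stage/condition.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "simulate", 2, 60)
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 0
  m <- 2147483647
  for (cc in utf8ToInt(key)) {
    h <- (h * 31 + cc) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
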