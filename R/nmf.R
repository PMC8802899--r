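#' Nonnegative double SVD initialization
#'
#' Deterministic NMF initialization: the leading `rank` singular triplets of
#' `D` are split into their nonnegative parts, the larger-norm part of each
#' is kept, and zeros are then filled with the matrix mean so that the
#' multiplicative updates (whose zeros are absorbing) can move every entry.
#' Determinism here is what makes the whole decomposition unique and
#' reproducible for a given input.
#'
#' @param D Nonnegative matrix (m x n).
#' @param rank Factorization rank.
#' @return List with `W` (m x rank) and `C` (rank x n).
#' @keywords internal
nndsvd_init <- function(D, rank) {
  sv <- svd(D, nu = rank, nv = rank)
  m <- nrow(D); n <- ncol(D)
  W <- matrix(0, m, rank)
  C <- matrix(0, rank, n)

  # leading component: Perron vectors are sign-ambiguous, take magnitudes
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  C[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])

  if (rank >= 2) {
    for (j in 2:rank) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
      n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        norm_prod <- n_up * n_vp
        if (norm_prod > 0) {
          scale <- sqrt(sv$d[j] * norm_prod)
          W[, j] <- scale * up / n_up
          C[j, ] <- scale * vp / n_vp
        }
      } else {
        norm_prod <- n_un * n_vn
        if (norm_prod > 0) {
          scale <- sqrt(sv$d[j] * norm_prod)
          W[, j] <- scale * un / n_un
          C[j, ] <- scale * vn / n_vn
        }
      }
    }
  }
  fill <- mean(D)
  W[W <= 0] <- fill
  C[C <= 0] <- fill
  list(W = W, C = C)
}

#' Muscle synergy extraction by nonnegative matrix factorization
#'
#' Factorizes a nonnegative burst matrix `D` (muscles x time) as
#' \eqn{D \approx W C} with `W` (muscles x rank) the muscle contribution
#' vectors and `C` (rank x time) the activation patterns. Uses
#' Frobenius-norm multiplicative updates with deterministic nonnegative
#' double-SVD initialization, stopping when the relative change of the
#' objective falls below `tol` or after `max_iter` iterations. The same
#' input always yields the same decomposition.
#'
#' @param D Nonnegative matrix, e.g. from [burst_matrix()].
#' @param rank Factorization rank (number of synergies), between 1 and
#'   `nrow(D)`.
#' @param tol Relative objective-change tolerance.
#' @param max_iter Maximum iterations.
#' @return An object of class `synergy_decomposition`: list with `W`, `C`,
#'   `rank`, `vaf_global`, `vaf_per_muscle`, `converged`, `iterations`, and
#'   the per-iteration `objective` trajectory.
#' @export
#' @examples
#' D <- matrix(runif(5 * 50), 5)
#' s <- nmf(D, 2)
#' glance(s)
nmf <- function(D, rank, tol = 1e-6, max_iter = 10000) {
  D <- unclass(D)
  if (any(D < 0)) stop_bad("`D` must be nonnegative")
  if (rank < 1 || rank > nrow(D)) {
    stop_bad("`rank` must be between 1 and nrow(D)")
  }
  init <- nndsvd_init(D, rank)
  fit <- nmf_mu_cpp(D, init$W, init$C, tol, as.integer(max_iter))
  W <- fit$W; C <- fit$C
  obj <- as.numeric(fit$objective)
  converged <- fit$converged
  it <- fit$iterations

  v <- vaf(D, W, C)
  muscles <- rownames(D) %||% paste0("ch", seq_len(nrow(D)))
  rownames(W) <- muscles
  structure(list(W = W, C = C, rank = as.integer(rank),
                 vaf_global = v$global, vaf_per_muscle = v$per_muscle,
                 converged = converged, iterations = it, objective = obj,
                 muscles = muscles),
            class = "synergy_decomposition")
}

#' Variance accounted for by a factorization
#'
#' Uncentered VAF: \eqn{1 - \sum (D - WC)^2 / \sum D^2}, computed globally
#' and per muscle row. The uncentered form is the synergy-analysis standard;
#' baseline (mean) activity is meaningful here, so a centered R-squared
#' would discard part of the signal being modelled.
#'
#' @param D Original nonnegative matrix.
#' @param W,C Factor matrices with conforming shapes.
#' @return List with `global` and named `per_muscle` fractions.
#' @export
vaf <- function(D, W, C) {
  D <- unclass(D)
  if (!all(dim(D) == c(nrow(W), ncol(C))) || ncol(W) != nrow(C)) {
    stop_bad("shapes of D, W, C do not conform")
  }
  sst <- sum(D^2)
  if (sst == 0) stop_bad("`D` is all zero; VAF undefined")
  R <- D - W %*% C
  per_row_sst <- rowSums(D^2)
  per_row <- ifelse(per_row_sst > 0, 1 - rowSums(R^2) / per_row_sst, 1)
  names(per_row) <- rownames(D)
  list(global = 1 - sum(R^2) / sst, per_muscle = per_row)
}

#' Minimum-rank selection by the VAF threshold
#'
#' Scans ranks 1..`max_rank` in ascending order and selects the smallest
#' whose global VAF reaches `threshold` (ties broken by the scan order).
#' If no rank reaches the threshold, rank `max_rank` is reported with the
#' discard flag set. The decomposition is also flagged discarded when any
#' per-muscle VAF at the selected rank falls below the same threshold.
#'
#' @param D Nonnegative burst matrix.
#' @param threshold VAF threshold in (0, 1]; 0.9 is the conventional cut.
#' @param max_rank Largest rank considered (the number of muscles).
#' @param ... Passed to [nmf()].
#' @return An object of class `rank_selection`: list with `rank`,
#'   `discarded`, `per_rank` (tibble of rank and vaf_global), and
#'   `decomposition` (the fit at the selected rank).
#' @export
select_rank <- function(D, threshold = 0.9, max_rank = min(5, nrow(D)), ...) {
  if (threshold <= 0 || threshold > 1) stop_bad("`threshold` must be in (0, 1]")
  fits <- vector("list", max_rank)
  vafs <- numeric(max_rank)
  selected <- NA_integer_
  for (r in seq_len(max_rank)) {
    fits[[r]] <- nmf(unclass(D), r, ...)
    vafs[r] <- fits[[r]]$vaf_global
    if (is.na(selected) && vafs[r] >= threshold) selected <- r
  }
  discarded <- is.na(selected)
  if (discarded) selected <- max_rank
  fit <- fits[[selected]]
  if (any(fit$vaf_per_muscle < threshold)) discarded <- TRUE
  structure(list(rank = selected, discarded = discarded,
                 per_rank = tibble::tibble(rank = seq_len(max_rank),
                                           vaf_global = vafs[seq_len(max_rank)]),
                 decomposition = fit, threshold = threshold),
            class = "rank_selection")
}

#' Normalize synergy weights and activation patterns
#'
#' Scales each column of `W` and each row of `C` to a maximum of 1 (zero
#' columns/rows are left at zero), the convention used for cross-subject
#' comparison of contribution vectors and activation patterns. Note this
#' breaks the product `W %*% C`; the stored VAF values still describe the
#' unnormalized fit.
#'
#' @param S A `synergy_decomposition`.
#' @return The decomposition with normalized `W` and `C`.
#' @export
normalize_synergies <- function(S) {
  stopifnot(inherits(S, "synergy_decomposition"))
  wmax <- apply(S$W, 2, max)
  cmax <- apply(S$C, 1, max)
  S$W <- sweep(S$W, 2, ifelse(wmax > 0, wmax, 1), "/")
  S$C <- sweep(S$C, 1, ifelse(cmax > 0, cmax, 1), "/")
  S$normalized <- TRUE
  S
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   non-zero entry.
#' @return `a . b / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_bad("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_bad("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Pairwise cosine similarity across a set of vectors
#'
#' All unordered pairs, as used to compare synergy vectors across subjects
#' within a (position, angle, synergy) grouping.
#'
#' @param items List of numeric vectors (>= 2) of equal length.
#' @return List with `mean` (mean over unordered pairs) and `matrix` (the
#'   full symmetric similarity matrix, unit diagonal).
#' @export
pairwise_similarity <- function(items) {
  k <- length(items)
  if (k < 2) stop_bad("need at least 2 items")
  M <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      M[i, j] <- M[j, i] <- cosine_similarity(items[[i]], items[[j]])
    }
  }
  list(mean = mean(M[upper.tri(M)]), matrix = M)
}

#' Match estimated synergies to reference synergies
#'
#' Greedy pairing by cosine similarity between columns of two weight (or
#' rows of two activation) matrices; used to align NMF components, whose
#' order is arbitrary, with ground-truth templates or another subject's
#' decomposition.
#'
#' @param est,ref Matrices with components in columns.
#' @return Integer vector: for each reference column, the matched estimate
#'   column.
#' @export
match_components <- function(est, ref) {
  k <- ncol(ref)
  sim <- matrix(0, k, ncol(est))
  for (i in seq_len(k)) {
    for (j in seq_len(ncol(est))) {
      sim[i, j] <- cosine_similarity(ref[, i], est[, j])
    }
  }
  assign <- integer(k)
  avail <- rep(TRUE, ncol(est))
  ord <- order(apply(sim, 1, max), decreasing = TRUE)
  for (i in ord) {
    j <- which.max(ifelse(avail, sim[i, ], -Inf))
    assign[i] <- j
    avail[j] <- FALSE
  }
  assign
}
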