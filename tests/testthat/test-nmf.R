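test_that("an exactly factorizable matrix is recovered with full VAF", {
  set.seed(1)
  W0 <- matrix(runif(5 * 2), 5)
  C0 <- matrix(runif(2 * 60), 2)
  D <- W0 %*% C0
  dec <- nmf(D, 2)
  expect_gt(dec$vaf_global, 1 - 1e-6)
  expect_true(all(dec$vaf_per_muscle > 1 - 1e-5))
  expect_true(all(dec$W >= 0) && all(dec$C >= 0))
})

test_that("an all-zero muscle row gets a near-zero weight row", {
  set.seed(2)
  D <- matrix(runif(5 * 40), 5)
  D[3, ] <- 0
  dec <- nmf(D, 2)
  expect_lt(max(dec$W[3, ]), 1e-4 * max(dec$W))
})

test_that("VAF matches hand arithmetic and handles degenerate input", {
  D <- rbind(c(1, 2), c(3, 4))
  W <- rbind(c(1, 0), c(0, 1))
  C <- rbind(c(1, 2), c(3, 0))
  v <- vaf(D, W, C)
  expect_equal(v$global, 1 - 16 / 30)
  expect_equal(unname(v$per_muscle), c(1, 1 - 16 / 25))
  expect_error(vaf(matrix(0, 2, 2), W, C), "all zero")
  expect_error(vaf(D, W, matrix(1, 3, 2)), "conform")
})

test_that("VAF is non-decreasing in rank and the objective non-increasing", {
  set.seed(3)
  D <- matrix(runif(5 * 200), 5)
  vafs <- vapply(1:5, function(r) nmf(D, r)$vaf_global, numeric(1))
  expect_true(all(diff(vafs) >= -1e-9))
  for (r in c(1, 3)) {
    obj <- nmf(D, r)$objective
    expect_true(all(diff(obj) <= 1e-8 * obj[-length(obj)]))
  }
})

test_that("the decomposition is deterministic for identical input", {
  set.seed(4)
  D <- matrix(runif(5 * 80), 5)
  d1 <- nmf(D, 3)
  d2 <- nmf(D, 3)
  expect_identical(d1$W, d2$W)
  expect_identical(d1$C, d2$C)
  expect_error(nmf(-D, 2), "nonnegative")
  expect_error(nmf(D, 0), "rank")
})

test_that("rank selection scans ascending and flags unreachable thresholds", {
  w <- matrix(runif(5), 5)
  D1 <- w %*% t(runif(50))          # exact nonnegative rank 1
  expect_equal(select_rank(D1)$rank, 1)
  expect_false(select_rank(D1)$discarded)

  set.seed(5)
  noisy <- matrix(runif(5 * 60), 5)
  sel <- select_rank(noisy, threshold = 1)
  expect_equal(sel$rank, 5)
  expect_true(sel$discarded)
  expect_equal(sel$per_rank$rank, 1:5)
  expect_error(select_rank(noisy, threshold = 0), "threshold")
})

test_that("synergy normalization scales columns and rows to max 1", {
  S <- structure(list(W = cbind(c(0.2, 0.4), c(0, 0)),
                      C = rbind(c(1, 2, 4), c(0, 0, 0)),
                      rank = 2), class = "synergy_decomposition")
  out <- normalize_synergies(S)
  expect_equal(out$W[, 1], c(0.5, 1))
  expect_equal(out$W[, 2], c(0, 0))          # zero column untouched
  expect_equal(out$C[1, ], c(0.25, 0.5, 1))
  expect_identical(normalize_synergies(out)$W, out$W)
})

test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("pairwise similarity averages all unordered pairs", {
  same <- pairwise_similarity(list(c(1, 2), c(1, 2), c(2, 4)))
  expect_equal(same$mean, 1)
  orth <- pairwise_similarity(list(c(1, 0), c(0, 1)))
  expect_equal(orth$mean, 0)
  expect_equal(dim(orth$matrix), c(2, 2))
  expect_error(pairwise_similarity(list(c(1, 2))), "at least 2")
})

test_that("rank-2 NMF recovers known templates under 10% noise", {
  fs <- 50
  t_ms <- seq(0, 9000 - 1000 / fs, by = 1000 / fs)
  trend <- default_trend()
  Tm <- trend_templates(trend, t_ms, 3000, 500, 5000)
  tab <- trend$table[trend$table$position == 1 & trend$table$angle == 0, ]
  for (seed in 1:3) {
    set.seed(seed)
    D <- t(sapply(seq_len(nrow(tab)), function(i) {
      (tab$a[i] * Tm[1, ] + tab$b[i] * Tm[2, ]) *
        exp(rnorm(length(t_ms), 0, 0.1))
    }))
    rownames(D) <- tab$muscle
    dec <- sort_synergies(nmf(normalize_burst(D), 2))
    pairing <- match_components(t(dec$C), t(Tm))
    cs <- vapply(1:2, function(i)
      cosine_similarity(dec$C[pairing[i], ], Tm[i, ]), numeric(1))
    expect_true(all(cs >= 0.9))
  }
})

test_that("tidiers expose weights, activations and fit summaries", {
  set.seed(6)
  D <- matrix(runif(5 * 30), 5,
              dimnames = list(MUSC, NULL))
  dec <- nmf(D, 2)
  w <- tidy(dec, "W")
  expect_equal(nrow(w), 10)
  expect_setequal(unique(w$muscle), MUSC)
  cc <- tidy(dec, "C")
  expect_equal(nrow(cc), 2 * 30)
  g <- glance(dec)
  expect_equal(g$rank, 2)
  expect_true(g$vaf_global <= 1)
})
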