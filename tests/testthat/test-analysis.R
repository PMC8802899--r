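test_that("central-window means take the middle of the burst", {
  expect_equal(central_window_mean(rep(3.2, 100), fs = 10, window_s = 4), 3.2)
  expect_equal(central_window_mean(c(1, 2, 3, 4), fs = 1, window_s = 4), 2.5)
  expect_error(central_window_mean(1:10, fs = 10, window_s = 4), "exceeds")
  # symmetric trapezoid with a plateau longer than the window -> plateau value
  fs <- 100
  t_ms <- seq(0, 7000, by = 1000 / fs)
  x <- 5 * spinalsynergy:::trapezoid_profile(t_ms, 500, 500, 5000)
  expect_equal(central_window_mean(x, fs, 4), 5, tolerance = 1e-9)
})

test_that("identical groups give a null contrast, separated groups reject", {
  df <- tidyr::expand_grid(subject = 1:10, position = 1, angle = c(0, 20),
                           muscle = "RF")
  df$amplitude <- 1
  con <- compare_conditions(df)
  expect_equal(con$statistic, 0)
  expect_equal(con$p_value, 1)
  expect_false(con$significant)

  set.seed(1)
  df2 <- df
  df2$amplitude <- ifelse(df2$angle == 0, rnorm(10, 10, 0.5), rnorm(10, 5, 0.5))
  con2 <- compare_conditions(df2)
  expect_true(con2$significant)
  expect_gt(con2$mean1, con2$mean2)
  expect_equal(attr(con2, "correction"), "none")
})

test_that("contrast tables cover adjacent angles and position pairs", {
  set.seed(2)
  df <- tidyr::expand_grid(subject = 1:6, position = c(1, 2),
                           angle = c(0, 20, 60, 90), muscle = c("RF", "ST"))
  df$amplitude <- rnorm(nrow(df), 1, 0.1)
  con <- compare_conditions(df)
  # per muscle: 3 adjacent-angle pairs x 2 positions + 4 position pairs
  expect_equal(nrow(con), 2 * (3 * 2 + 4))
  expect_false(any(con$group1 == "0" & con$group2 == "60"))
})

test_that("label permutations reject at the nominal rate", {
  set.seed(7)
  w <- rnorm(34, 0.5, 0.1)
  reject <- vapply(1:1000, function(i) {
    lab <- sample(rep(c(0, 20), each = 17))
    df <- tibble::tibble(subject = seq_along(w), position = 1, angle = lab,
                         muscle = "ST", weight = w)
    any(contribution_vector_tests(df)$significant)
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("the trend checklist evaluates its items from supplied quantities", {
  # fabricate contrasts: all marked contrasts significant in the right way
  set.seed(3)
  means <- tidyr::expand_grid(subject = 1:17, position = c(1, 2),
                              angle = c(0, 20, 60, 90), muscle = MUSC)
  base <- c(RF = 1, VL = 1, VM = 1, ST = 0.2, BF = 0.2)
  shape <- function(m, p, a) {
    if (m %in% EXT) {
      v <- c(`0` = 1, `20` = if (p == 1) 0.7 else 0.4,
             `60` = if (p == 1) 0.45 else 0.38, `90` = 0.37)[as.character(a)]
      if (m == "RF" && p == 2 && a > 0) v <- v * 0.6
      v
    } else if (m == "ST") c(`0` = 0.2, `20` = 0.5, `60` = 0.5, `90` = 0.5)[as.character(a)]
    else 0.3
  }
  means$amplitude <- mapply(shape, means$muscle, means$position, means$angle) *
    rlnorm(nrow(means), 0, 0.1)
  con <- compare_conditions(means)

  model_w <- fake_weights(c(RF = 0.05, VL = 0.02, VM = 0.04, ST = 1, BF = 0.3))
  dataw <- tidyr::expand_grid(subject = 1:4, position = 1,
                              angle = c(0, 90), muscle = MUSC)
  dataw$weight <- with(dataw, ifelse(muscle == "ST",
                                     ifelse(angle == 0, 0.9, 0.7),
                                     ifelse(muscle %in% EXT,
                                            ifelse(angle == 0, 0.05, 0.15), 0.8)))
  flip_w <- fake_weights(c(RF = 1, VL = 0.2, VM = 0.1, ST = 0.05, BF = 0.02))
  equal_w <- fake_weights(c(RF = 0.9, VL = 0.5, VM = 0.4, ST = 0.85, BF = 0.4))

  cl <- trend_checklist(con, model_w, data_weights = dataw,
                        flip_weights = flip_w, equal_weights = equal_w)
  expect_true(all(cl$pass))
  expect_equal(nrow(cl), 8)

  # a flipped run fed in as the 0-degree preset fails the antagonist item
  cl2 <- trend_checklist(con, flip_w, data_weights = dataw,
                         flip_weights = model_w, equal_weights = equal_w)
  expect_false(cl2$pass[cl2$item == "synergy2-antagonist-bias-at-0"])
  expect_false(cl2$pass[cl2$item == "bias-flip-under-senExtInt"])
  # missing optional inputs yield NA, not errors
  cl3 <- trend_checklist(con, model_w)
  expect_true(is.na(cl3$pass[cl3$item == "equal-input-cancellation"]))
})

test_that("the synergy bias index reads the low-activity group's loading", {
  expect_gt(synergy_bias(fake_weights(c(RF = 0.1, VL = 0, VM = 0.05,
                                        ST = 1, BF = 0.2))), 0.5)
  expect_lt(synergy_bias(fake_weights(c(RF = 1, VL = 0.3, VM = 0.1,
                                        ST = 0.1, BF = 0))), -0.5)
  two_runs <- dplyr::bind_rows(
    fake_weights(c(RF = 1, VL = 0, VM = 0, ST = 0, BF = 0), run = 1),
    fake_weights(c(RF = 0, VL = 0, VM = 0, ST = 1, BF = 0), run = 2))
  expect_equal(synergy_bias(two_runs), 0)
})
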