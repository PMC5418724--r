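test_that("r_squared matches its closed form", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 1, 3)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(1, 1), "2 points")
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("ratio targets are 1 at neutral and match a group-by oracle", {
  fm <- fm_drop_pos(medium_features())
  grid <- medium_session()$config$grid
  tg <- compute_targets(fm, grid, seed = 17L)
  K <- length(tg$classes)
  # neutral cell of the statistics split: ratios exactly 1
  expect_equal(as.vector(tg$mean_targets$stats[, 1, ]),
    rep(1, K * ncol(fm$X)))
  expect_equal(as.vector(tg$var_targets$stats[, 1, ]),
    rep(1, K * ncol(fm$X)), tolerance = 1e-9)
  # independent aggregate() oracle for a handful of cells
  sp <- split_features(fm,
    fractions = c(train = 0.5, validation = 0.2, test = 0.3),
    fold = 1L, seed = 17L)
  df <- data.frame(v = sp$train$X[, 1], class = sp$train$meta$class,
    position = sp$train$meta$position)
  agg <- stats::aggregate(v ~ class + position, df, mean)
  for (k in seq_len(K)) {
    m0 <- agg$v[agg$class == tg$classes[k] & agg$position == 1]
    for (q in c(3, 7, 13)) {
      mq <- agg$v[agg$class == tg$classes[k] & agg$position == q]
      expect_equal(tg$mean_targets$stats[k, q, 1], mq / m0)
    }
  }
})

test_that("ratio targets are invariant to a global amplitude rescaling", {
  fm <- fm_drop_pos(small_features())
  grid <- small_session()$config$grid
  tg1 <- compute_targets(fm, grid, seed = 2L)
  fm2 <- fm
  amp <- fm$columns$feature %in% c("mav", "wl")
  # a global gain change scales amplitude features and their variances
  fm2$X[, amp] <- fm2$X[, amp] * 3.7
  tg2 <- compute_targets(fm2, grid, seed = 2L)
  expect_equal(tg2$mean_targets$stats, tg1$mean_targets$stats, tolerance = 1e-12)
  expect_equal(tg2$var_targets$test, tg1$var_targets$test, tolerance = 1e-9)
})

test_that("doubling one position's amplitudes doubles its MAV mean ratio", {
  fm <- fm_drop_pos(small_features())
  grid <- small_session()$config$grid
  fm2 <- fm
  amp <- which(fm$columns$feature == "mav")
  rows <- fm$meta$position == 4
  fm2$X[rows, amp] <- fm2$X[rows, amp] * 2
  tg1 <- compute_targets(fm, grid, seed = 2L)
  tg2 <- compute_targets(fm2, grid, seed = 2L)
  expect_equal(tg2$mean_targets$stats[, 4, amp],
    2 * tg1$mean_targets$stats[, 4, amp], tolerance = 1e-12)
  expect_equal(tg2$mean_targets$stats[, 5, amp],
    tg1$mean_targets$stats[, 5, amp], tolerance = 1e-12)
})

test_that("the bank forward pass equals a hand-computed tanh composition", {
  grid <- position_grid()
  theta <- matrix(seq(-0.8, 0.7, length.out = 16), 16, 1)
  bank <- structure(list(
    theta = theta,
    info = data.frame(moment = "mean", class = "open", channel = 1L,
      feature = "mav", mode = "ratio", informative = TRUE, constant = 1,
      r2 = NA_real_),
    classes = "open", columns = data.frame(channel = 1L, feature = "mav"),
    angles = NULL, grid = grid,
    neutral = NULL, mode = matrix("ratio", 1, 1), muscle_set = "combined",
    seed = 1L
  ), class = "ratio_bank")
  pos <- wrist_position(30, -10, 40)
  x <- as.numeric(pos) / grid$end_range_deg
  manual <- 0
  for (j in 1:3) {
    a <- sum(x * theta[(j - 1) * 3 + 1:3, 1]) + theta[9 + j, 1]
    manual <- manual + theta[12 + j, 1] * tanh(a)
  }
  manual <- manual + theta[16, 1]
  # the var half of the bank layout reuses the same single network column
  pr <- predict_ratios(bank, pos)
  expect_equal(unname(pr$mean[1, 1]), manual, tolerance = 1e-12)
})

test_that("bank gradients match numerical differentiation", {
  withr::with_seed(33, {
    X <- matrix(runif(13 * 3, -1, 1), 13, 3)
    Y <- matrix(rnorm(13 * 2), 13, 2)
    th <- matrix(rnorm(16 * 2, sd = 0.5), 16, 2)
    an <- myowrist:::bank_loss_grad(th, X, Y)$grad
    num <- matrix(0, 16, 2)
    eps <- 1e-6
    for (i in 1:16) for (r in 1:2) {
      tp <- th; tp[i, r] <- tp[i, r] + eps
      tm <- th; tm[i, r] <- tm[i, r] - eps
      num[i, r] <- (myowrist:::bank_loss(tp, X, Y)[r] -
        myowrist:::bank_loss(tm, X, Y)[r]) / (2 * eps)
    }
    expect_equal(an, num, tolerance = 1e-6)
  })
})

test_that("fitted bank recovers the smooth position dependence", {
  fm <- fm_drop_pos(medium_features())
  cfg <- medium_session()$config
  tg <- compute_targets(fm, cfg$grid, seed = 17L)
  bank <- fit_ratio_bank(tg, seed = 23L)
  info <- bank$info
  # amplitude features are informative, and their mean networks fit well
  amp <- info$feature %in% c("mav", "wl")
  expect_true(all(info$informative[amp & info$moment == "mean"]))
  expect_gt(mean(info$r2[amp & info$moment == "mean"]), 0.7)
  # variance targets are noisier: lower r-squared than the mean networks
  expect_lt(mean(info$r2[amp & info$moment == "var"]),
    mean(info$r2[amp & info$moment == "mean"]))
  # predictions at neutral are near unit ratio for informative networks
  pr <- predict_ratios(bank, wrist_position(0, 0, 0))
  amp_cols <- which(bank$columns$feature %in% c("mav", "wl"))
  expect_equal(as.vector(pr$mean[, amp_cols]),
    rep(1, length(bank$classes) * length(amp_cols)), tolerance = 0.1)
  # outputs vary smoothly with angle
  d <- unname(predict_ratios(bank, wrist_position(30.5, 0, 0))$mean[1, amp_cols[1]] -
    predict_ratios(bank, wrist_position(30, 0, 0))$mean[1, amp_cols[1]])
  expect_lt(abs(d), 0.05)
})

test_that("targets with no reproducible position structure give near-zero r2", {
  # scrambling each split's position axis independently leaves the angle
  # inputs intact but removes any signal the training targets share with
  # the held-out targets, so test r-squared must collapse
  fm <- fm_drop_pos(medium_features())
  cfg <- medium_session()$config
  tg <- compute_targets(fm, cfg$grid, seed = 17L)
  for (i in seq_along(tg$mean_targets)) {
    perm <- withr::with_seed(40L + i, sample(13))
    tg$mean_targets[[i]] <- tg$mean_targets[[i]][, perm, ]
    tg$var_targets[[i]] <- tg$var_targets[[i]][, perm, ]
  }
  bank <- fit_ratio_bank(tg, seed = 23L)
  amp <- bank$info$feature %in% c("mav", "wl") & bank$info$moment == "mean"
  expect_lt(mean(bank$info$r2[amp]), 0.2)
})

test_that("bank training is deterministic given its seed", {
  fm <- fm_drop_pos(small_features())
  tg <- compute_targets(fm, small_session()$config$grid, seed = 2L)
  b1 <- fit_ratio_bank(tg, seed = 5L, max_iter = 60)
  b2 <- fit_ratio_bank(tg, seed = 5L, max_iter = 60)
  expect_identical(b1$theta, b2$theta)
})
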