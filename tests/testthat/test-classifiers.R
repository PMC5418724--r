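test_that("stratified split respects the 50/20/30 fractions per cell", {
  fm <- small_features()
  sp <- split_features(fm, fold = 1L, seed = 3L)
  cell <- function(f) table(f$meta$class, f$meta$position)
  n_cell <- nrow(fm$X) / (4 * 13)
  expect_true(all(cell(sp$train) == round(0.5 * n_cell)))
  expect_true(all(cell(sp$validation) == round(0.2 * n_cell)))
  expect_true(all(cell(sp$test) == n_cell - round(0.5 * n_cell) - round(0.2 * n_cell)))
})

test_that("folds partition the rows and fold 2 swaps train and test", {
  fm <- small_features()
  key <- function(f) paste(f$meta$class, f$meta$position, f$meta$rep, f$meta$window)
  f1 <- split_features(fm, fold = 1L, seed = 3L)
  f2 <- split_features(fm, fold = 2L, seed = 3L)
  all_rows <- sort(key(fm_rows(fm, seq_len(nrow(fm$X)))))
  expect_equal(sort(c(key(f1$train), key(f1$validation), key(f1$test))), all_rows)
  expect_length(intersect(key(f1$train), key(f1$test)), 0)
  # fold-1 test rows are exactly the fold-2 training rows
  expect_setequal(key(f1$test), key(f2$train))
  expect_setequal(key(f1$train), key(f2$test))
  expect_setequal(key(f1$validation), key(f2$validation))
})

test_that("LDA separates well-separated Gaussian classes at the Bayes boundary", {
  fm <- gauss_fixture(n = 300, sep = 6)
  sp <- split_features(fm, fold = 1L, seed = 1L)
  m <- fit_classifier(classifier_spec("LDA"), sp$train, sp$validation)
  err <- classification_error(predict(m, sp$test), sp$test$meta$class)
  expect_lte(err, 1)
  # decision boundary near x1 = 0: probe points straddling it
  probe <- cbind(seq(-0.5, 0.5, by = 0.05), 0)
  colnames(probe) <- c("f1", "f2")
  pred <- predict(m, probe)
  flip <- which(pred[-1] != pred[-length(pred)])
  expect_length(flip, 1)
  expect_lt(abs(probe[flip, 1]), 0.11)
})

test_that("LDA/QDA parameters equal closed-form estimates", {
  fm <- gauss_fixture(n = 60, sep = 3, seed = 12L)
  sp <- split_features(fm, fold = 1L, seed = 1L)
  for (kind in c("LDA", "QDA")) {
    m <- fit_classifier(classifier_spec(kind), sp$train, sp$validation)
    # recompute the closed forms by hand on the z-scored training data
    Xs <- sweep(sweep(sp$train$X, 2, m$center), 2, m$scale, `/`)
    y <- sp$train$meta$class
    for (k in seq_along(m$classes)) {
      Xi <- Xs[y == m$classes[k], ]
      expect_equal(m$model$means[k, ], colMeans(Xi), tolerance = 1e-12,
        ignore_attr = TRUE)
    }
    if (kind == "QDA") {
      Xi <- Xs[y == m$classes[1], ]
      S <- crossprod(sweep(Xi, 2, colMeans(Xi))) / (nrow(Xi) - 1)
      S <- S + diag(1e-6 * sum(diag(S)) / 2, 2)
      expect_equal(m$model$covs[[1]], S, tolerance = 1e-12, ignore_attr = TRUE)
    } else {
      Sp <- Reduce(`+`, lapply(m$classes, function(cl) {
        Xi <- Xs[y == cl, ]
        crossprod(sweep(Xi, 2, colMeans(Xi)))
      })) / (nrow(Xs) - 2)
      Sp <- Sp + diag(1e-6 * sum(diag(Sp)) / 2, 2)
      expect_equal(m$model$covs[[1]], Sp, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("discriminant predictions agree with MASS on a shared fixture", {
  fm <- gauss_fixture(n = 150, sep = 3, seed = 21L)
  sp <- split_features(fm, fold = 1L, seed = 2L)
  m <- fit_classifier(classifier_spec("LDA"), sp$train, sp$validation)
  Xs <- sweep(sweep(sp$train$X, 2, m$center), 2, m$scale, `/`)
  Xt <- sweep(sweep(sp$test$X, 2, m$center), 2, m$scale, `/`)
  ref <- MASS::lda(Xs, grouping = sp$train$meta$class)
  agree <- mean(predict(m, sp$test) ==
    as.character(predict(ref, Xt)$class))
  expect_gte(agree, 0.99)
  mq <- fit_classifier(classifier_spec("QDA"), sp$train, sp$validation)
  refq <- MASS::qda(Xs, grouping = sp$train$meta$class)
  agree_q <- mean(predict(mq, sp$test) ==
    as.character(predict(refq, Xt)$class))
  expect_gte(agree_q, 0.99)
})

test_that("prediction is deterministic, order-equivariant, and closed-form", {
  fm <- gauss_fixture(n = 100, sep = 10, seed = 31L)
  sp <- split_features(fm, fold = 1L, seed = 1L)
  m <- fit_classifier(classifier_spec("LDA"), sp$train, sp$validation)
  expect_equal(classification_error(predict(m, sp$train), sp$train$meta$class), 0)
  perm <- sample(nrow(sp$test$X))
  expect_identical(predict(m, sp$test)[perm], predict(m, fm_rows(sp$test, perm)))
  # two-point fixture: scores from the textbook Gaussian discriminant
  model <- m$model
  x <- sweep(sweep(sp$test$X[1:2, ], 2, m$center), 2, m$scale, `/`)
  sc <- myowrist:::gauss_disc_scores(model, x)
  Sinv <- solve(model$covs[[1]])
  for (k in 1:2) {
    mu <- model$means[k, ]
    manual <- x %*% Sinv %*% mu - 0.5 * drop(mu %*% Sinv %*% mu) + log(model$priors[k])
    expect_equal(sc[, k], drop(manual), tolerance = 1e-8)
  }
})

test_that("classification error counts misclassifications in percent", {
  expect_equal(classification_error(c("a", "a"), c("a", "a")), 0)
  expect_equal(classification_error(c("a", "a"), c("b", "b")), 100)
  expect_equal(classification_error(rep("a", 10), c(rep("a", 7), rep("b", 3))), 30)
  expect_error(classification_error("a", c("a", "b")), "lengths")
  # position-wise averaging weights positions equally
  pred <- c("a", "a", "a", "a", "a", "a")
  truth <- c("a", "b", "a", "a", "a", "a")
  posn <- c(1, 1, 2, 2, 2, 2)
  expect_equal(classification_error(pred, truth, posn), mean(c(50, 0)))
})

test_that("the MLPANN solves XOR while LDA cannot", {
  errs <- vapply(1:10, function(s) {
    fm <- xor_fixture(seed = 100 + s)
    sp <- split_features(fm, fold = 1L, seed = s)
    m <- fit_classifier(classifier_spec("MLPANN", seed = s, max_iter = 200),
      sp$train, sp$validation)
    classification_error(predict(m, sp$test), sp$test$meta$class)
  }, numeric(1))
  expect_lte(mean(errs), 5)
  fm <- xor_fixture(seed = 101)
  sp <- split_features(fm, fold = 1L, seed = 1L)
  lda_err <- classification_error(
    predict(fit_classifier(classifier_spec("LDA"), sp$train, sp$validation), sp$test),
    sp$test$meta$class)
  expect_gt(lda_err, 30)
  # a linear-activation network cannot do better than linear either
  lnn_err <- classification_error(
    predict(fit_classifier(classifier_spec("LNN", seed = 1L), sp$train, sp$validation),
      sp$test), sp$test$meta$class)
  expect_lt(mean(errs), lnn_err)
})

test_that("the linear-activation network behaves as a linear softmax model", {
  fm <- gauss_fixture(n = 250, sep = 2.5, seed = 51L)
  sp <- split_features(fm, fold = 1L, seed = 4L)
  m <- fit_classifier(classifier_spec("LNN", seed = 2L, max_iter = 400),
    sp$train, sp$validation)
  Xs <- sweep(sweep(sp$train$X, 2, m$center), 2, m$scale, `/`)
  Xt <- sweep(sweep(sp$test$X, 2, m$center), 2, m$scale, `/`)
  ref <- nnet::multinom(cl ~ ., data = data.frame(Xs, cl = sp$train$meta$class),
    trace = FALSE)
  agree <- mean(predict(m, sp$test) ==
    as.character(predict(ref, newdata = data.frame(Xt))))
  expect_gte(agree, 0.99)
})

test_that("network training is reproducible given the spec seed", {
  fm <- xor_fixture(seed = 61L)
  sp <- split_features(fm, fold = 1L, seed = 6L)
  spec <- classifier_spec("MLPANN", seed = 9L, max_iter = 100, restarts = 1)
  m1 <- fit_classifier(spec, sp$train, sp$validation)
  m2 <- fit_classifier(spec, sp$train, sp$validation)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  expect_equal(m1$model$theta, m2$model$theta)
})

test_that("prediction rejects mismatched column layouts", {
  fm <- gauss_fixture()
  sp <- split_features(fm, fold = 1L, seed = 1L)
  m <- fit_classifier(classifier_spec("LDA"), sp$train, sp$validation)
  expect_error(predict(m, matrix(0, 2, 5)), "column layout")
})
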