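# classifier settings kept light: these tests exercise the experiment
# drivers' bookkeeping, not asymptotic classifier accuracy
cheap_specs <- function(seed = 1L) {
  lapply(c("LDA", "QDA", "LNN", "MLPANN"), classifier_spec,
    seed = seed, max_iter = 40L, restarts = 1L)
}

grid_features <- function() {
  cached("grid_features", {
    fm <- small_features()
    # thin the windows to keep 24 classifier fits quick
    keep <- fm$meta$window %% 3 == 1
    list(
      extrinsic = fm_rows(fm_cols(fm, fm$columns$channel %in% 1:9 |
        is.na(fm$columns$channel)), keep),
      intrinsic = fm_rows(fm_cols(fm, fm$columns$channel %in% 10:13 |
        is.na(fm$columns$channel)), keep),
      combined = fm_rows(fm, keep)
    )
  })
}

test_that("the experiment grid has 24 cells and reproduces under a fixed seed", {
  feats <- grid_features()
  gr <- cached("grid_result_cheap", run_grid(feats, cheap_specs(), seed = 7L))
  expect_equal(nrow(gr$errors), 4 * 2 * 3)
  expect_true(all(gr$errors$error >= 0 & gr$errors$error <= 100))
  expect_equal(nrow(gr$pos_change), 12)
  # relative-change table is exact arithmetic on the stored errors
  for (i in seq_len(nrow(gr$pos_change))) {
    sel <- gr$errors$classifier == gr$pos_change$classifier[i] &
      gr$errors$muscle_set == gr$pos_change$muscle_set[i]
    e <- gr$errors[sel, ]
    a <- e$error[e$feature_set == "TDAR"]
    b <- e$error[e$feature_set == "TDAR+POS"]
    if (a == 0) {
      expect_true(is.na(gr$pos_change$change_pct[i]))
    } else {
      expect_equal(gr$pos_change$change_pct[i], 100 * (a - b) / a)
    }
  }
  gr2 <- run_grid(feats, cheap_specs(), seed = 7L)
  expect_identical(gr$errors, gr2$errors)
})

test_that("wrist-position features do not degrade classification", {
  gr <- cached("grid_result_cheap", run_grid(grid_features(), cheap_specs(), seed = 7L))
  e <- gr$errors
  for (i in seq_len(nrow(gr$pos_change))) {
    sel <- e$classifier == gr$pos_change$classifier[i] &
      e$muscle_set == gr$pos_change$muscle_set[i]
    a <- e$error[sel & e$feature_set == "TDAR"]
    b <- e$error[sel & e$feature_set == "TDAR+POS"]
    expect_lte(b, a + 2) # never worse beyond chance-level fluctuation
  }
  # the nonlinear network exploits the position information
  mlp <- gr$pos_change$change_pct[gr$pos_change$classifier == "MLPANN" &
    gr$pos_change$muscle_set == "combined"]
  expect_gt(mlp, 0)
})

test_that("error tables round-trip through CSV losslessly", {
  gr <- cached("grid_result_cheap", run_grid(grid_features(), cheap_specs(), seed = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(gr$errors, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$error, gr$errors$error, tolerance = 1e-12)
  expect_identical(back$classifier, gr$errors$classifier)
  expect_identical(back$feature_set, gr$errors$feature_set)
})

test_that("combining muscle sets does not hurt the discriminants", {
  feats <- grid_features()
  gr <- cached("grid_result_lda", {
    run_grid(feats, list(classifier_spec("LDA")), seed = 8L)
  })
  e <- gr$errors[gr$errors$feature_set == "TDAR", ]
  comb <- e$error[e$muscle_set == "combined"]
  expect_lte(comb, min(e$error[e$muscle_set != "combined"]) + 2)
})

test_that("subset search is exhaustive and agrees with a brute-force rerun", {
  fm <- fm_drop_pos(small_features())
  # miniature grid: four positions only
  fm4 <- fm_rows(fm, fm$meta$position <= 4)
  res <- subset_search(fm4, n_range = 1:4, seed = 9L)
  expect_equal(res$n_evaluated, choose(4, 1:4))
  expect_equal(res$n_evaluated[res$n == 2], 6)
  # independent brute force over all subsets of each size
  sp <- split_features(fm4, fold = 1L, seed = 9L)
  det <- attr(res, "details")
  for (n in c(2, 3)) {
    combos <- combn(4, n)
    errs <- vapply(seq_len(ncol(combos)), function(i) {
      m <- fit_classifier(classifier_spec("LDA"),
        fm_rows(sp$train, sp$train$meta$position %in% combos[, i]),
        fm_rows(sp$validation, sp$validation$meta$position %in% combos[, i]))
      classification_error(predict(m, sp$test), sp$test$meta$class,
        by_position = sp$test$meta$position)
    }, numeric(1))
    expect_equal(det[[as.character(n)]]$errors, errs)
    best <- which.min(errs)
    expect_equal(res$best_combination[res$n == n],
      paste(combos[, best], collapse = ","))
    expect_equal(res$error[res$n == n], min(errs))
  }
  # the full-grid subset equals training on everything
  full <- subset_search(fm4, n_range = 4, seed = 9L)
  expect_equal(full$n_evaluated, 1)
  expect_error(subset_search(fm4, n_range = 5), "n_range")
})

test_that("training paradigms coincide on a single-position dataset", {
  fm <- fm_drop_pos(medium_features())
  fm1 <- fm_rows(fm, fm$meta$position == 1)
  res <- compare_paradigms(fm1, seed = 10L)
  expect_equal(res$error[1], res$error[2])
  pe <- attr(res, "position_errors")
  expect_length(pe$paradigm1, 1)
})

test_that("both paradigms average exactly one error per position", {
  fm <- fm_drop_pos(small_features())
  res <- compare_paradigms(fm, seed = 11L)
  pe <- attr(res, "position_errors")
  expect_length(pe$paradigm1, 13)
  expect_length(pe$paradigm2, 13)
  expect_equal(res$error[1], mean(pe$paradigm1))
  expect_equal(res$error[2], mean(pe$paradigm2))
})

test_that("relative improvement handles equal and zero errors", {
  expect_equal(relative_improvement(10, 5), 50)
  expect_equal(relative_improvement(8, 8), 0)
  expect_true(is.na(relative_improvement(0, 5)))
})
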