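#' Simulate a multi-position feature dataset from neutral statistics
#'
#' For every (class, position) cell, draws each feature column
#' independently from a normal distribution whose mean is the
#' neutral-position mean scaled by the bank's predicted mean ratio (or
#' shifted by the predicted difference, for difference-mode features) and
#' whose variance is the neutral variance scaled by the predicted variance
#' ratio. This synthesizes the training data a subject would have produced
#' in all 13 wrist positions from recordings made only at neutral.
#' Non-positive predicted variances are clipped to a `1e-12` floor.
#'
#' @param neutral neutral-position statistics (`mean`, `variance`
#'   class-by-feature matrices), e.g. `targets$neutral` from
#'   [compute_targets()].
#' @param bank a fitted [fit_ratio_bank()].
#' @param grid the [position_grid()] to simulate over.
#' @param n_per_cell rows drawn per (class, position) cell.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `feature_matrix` with attribute `provenance = "adjusted"`.
#' @export
simulate_adjusted <- function(neutral, bank, grid, n_per_cell, seed = 1L) {
  simulate_cells(neutral, bank, grid, n_per_cell, seed, adjusted = TRUE)
}

#' Simulate a dataset from neutral statistics only
#'
#' As [simulate_adjusted()], but every position uses the unscaled
#' neutral-position distribution — the baseline a neutral-only training
#' session would give.
#'
#' @inheritParams simulate_adjusted
#' @param columns optional column metadata data.frame (`channel`,
#'   `feature`) for the output.
#' @return A `feature_matrix` with attribute `provenance = "unadjusted"`.
#' @export
simulate_unadjusted <- function(neutral, grid, n_per_cell, seed = 1L,
                                columns = NULL) {
  simulate_cells(neutral, bank = NULL, grid, n_per_cell, seed,
    adjusted = FALSE, columns = columns)
}

simulate_cells <- function(neutral, bank, grid, n_per_cell, seed, adjusted,
                           columns = NULL) {
  classes <- rownames(neutral$mean)
  if (is.null(classes) && !is.null(bank)) classes <- bank$classes
  K <- nrow(neutral$mean)
  if (is.null(classes)) classes <- as.character(seq_len(K))
  p <- ncol(neutral$mean)
  n_pos <- nrow(grid$positions)
  X <- matrix(0, K * n_pos * n_per_cell, p)
  meta <- data.frame(
    class = character(K * n_pos * n_per_cell), position = 0L, rep = NA_integer_,
    window = NA_integer_
  )
  row0 <- 0L
  withr::with_seed(seed, {
    for (q in seq_len(n_pos)) {
      if (adjusted) {
        pr <- predict_ratios(bank, grid$positions[q, ])
      }
      for (k in seq_len(K)) {
        if (adjusted) {
          mu <- ifelse(pr$mode[k, ] == "ratio",
            neutral$mean[k, ] * pr$mean[k, ],
            neutral$mean[k, ] + pr$mean[k, ])
          v <- pmax(neutral$variance[k, ] * pr$var[k, ], 1e-12)
        } else {
          mu <- neutral$mean[k, ]
          v <- pmax(neutral$variance[k, ], 1e-12)
        }
        rows <- row0 + seq_len(n_per_cell)
        X[rows, ] <- rep(mu, each = n_per_cell) +
          matrix(rnorm(n_per_cell * p), n_per_cell, p) *
            rep(sqrt(v), each = n_per_cell)
        meta$class[rows] <- classes[k]
        meta$position[rows] <- q
        row0 <- row0 + n_per_cell
      }
    }
  })
  cols <- if (!is.null(columns)) columns else if (!is.null(bank)) bank$columns else
    data.frame(channel = rep(NA_integer_, p), feature = paste0("f", seq_len(p)))
  colnames(X) <- ifelse(is.na(cols$channel), as.character(cols$feature),
    sprintf("ch%02d_%s", cols$channel, cols$feature))
  structure(list(
    X = X, meta = meta, columns = cols,
    muscle_set = if (!is.null(bank)) bank$muscle_set else "unknown",
    include_pos = FALSE
  ), class = "feature_matrix",
  provenance = if (adjusted) "adjusted" else "unadjusted")
}

#' Train on real vs simulated data, test on real data
#'
#' The three-dataset comparison: LDA classifiers trained on (1) real
#' multi-position data, (2) bank-adjusted simulated data and (3)
#' neutral-only (unadjusted) simulated data are all evaluated on the same
#' held-out real test rows from all wrist positions, with errors averaged
#' over positions. The headline quantity is the relative improvement of
#' adjusted over unadjusted training,
#' `100 * (err_unadj - err_adj) / err_unadj`.
#'
#' @param real a real (recorded) TDAR `feature_matrix`.
#' @param adjusted,unadjusted simulated `feature_matrix` objects with the
#'   same column layout (see [simulate_adjusted()]).
#' @param seed integer seed for the real train/test split.
#' @param spec classifier specification (default LDA, the study's choice).
#' @return List with `errors` (named: real, adjusted, unadjusted),
#'   `improvement_adjusted_pct`, `improvement_real_pct` and the split seed.
#' @export
three_dataset_comparison <- function(real, adjusted, unadjusted, seed = 1L,
                                     spec = classifier_spec("LDA")) {
  if (!identical(ncol(real$X), ncol(adjusted$X)) ||
    !identical(ncol(real$X), ncol(unadjusted$X))) {
    stop("column layouts of the three datasets differ")
  }
  sp <- split_features(real, fold = 1L, seed = seed)
  models <- list(
    real = fit_classifier(spec, sp$train, sp$validation),
    adjusted = fit_classifier(spec, adjusted, sp$validation),
    unadjusted = fit_classifier(spec, unadjusted, sp$validation)
  )
  errs <- vapply(models, function(m) {
    classification_error(predict(m, sp$test), sp$test$meta$class,
      by_position = sp$test$meta$position)
  }, numeric(1))
  list(
    errors = errs,
    improvement_adjusted_pct = relative_improvement(errs[["unadjusted"]], errs[["adjusted"]]),
    improvement_real_pct = relative_improvement(errs[["unadjusted"]], errs[["real"]]),
    seed = seed
  )
}
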