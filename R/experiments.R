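#' Relative improvement between two error rates
#'
#' `100 * (err_a - err_b) / err_a`; positive values mean `b` improves on
#' `a`. Returns `NA` (with no error) when `err_a` is zero.
#'
#' @param err_a,err_b error percentages.
#' @return Percentage change, or `NA_real_` when undefined.
#' @export
#' @examples
#' relative_improvement(10, 5)  # 50
relative_improvement <- function(err_a, err_b) {
  if (err_a == 0) return(NA_real_)
  100 * (err_a - err_b) / err_a
}

two_fold_error <- function(fm, spec, seed) {
  errs <- vapply(1:2, function(fold) {
    sp <- split_features(fm, fold = fold, seed = seed)
    m <- fit_classifier(spec, sp$train, sp$validation)
    classification_error(predict(m, sp$test), sp$test$meta$class,
      by_position = sp$test$meta$position)
  }, numeric(1))
  mean(errs)
}

#' Classifier x feature-set x muscle-set experiment grid
#'
#' Evaluates every classifier on the TDAR and TDAR+POS feature sets for
#' each muscle set, using two-fold cross-validated, position-averaged test
#' error (24 cells with the default four classifiers). Also tabulates the
#' relative error change from adding the POS features.
#'
#' @param features_by_muscle named list of `feature_matrix` objects (one
#'   per muscle set), each extracted with `include_pos = TRUE`.
#' @param specs list of [classifier_spec()]s.
#' @param seed integer split seed.
#' @return A `grid_result`: `errors` data.frame (classifier, feature_set,
#'   muscle_set, error) and `pos_change` data.frame with the relative
#'   improvement from POS per classifier and muscle set.
#' @export
run_grid <- function(features_by_muscle,
                     specs = lapply(c("LDA", "QDA", "LNN", "MLPANN"), classifier_spec),
                     seed = 1L) {
  stopifnot(length(names(features_by_muscle)) == length(features_by_muscle))
  rows <- list()
  for (ms in names(features_by_muscle)) {
    fm_pos <- features_by_muscle[[ms]]
    if (!fm_pos$include_pos) stop("feature matrices must include POS columns")
    sets <- list(TDAR = fm_drop_pos(fm_pos), `TDAR+POS` = fm_pos)
    for (fs in names(sets)) {
      for (spec in specs) {
        err <- two_fold_error(sets[[fs]], spec, seed)
        rows[[length(rows) + 1]] <- data.frame(
          classifier = spec$kind, feature_set = fs, muscle_set = ms, error = err
        )
      }
    }
  }
  errors <- do.call(rbind, rows)
  base <- errors[errors$feature_set == "TDAR", ]
  pos <- errors[errors$feature_set == "TDAR+POS", ]
  key <- paste(pos$classifier, pos$muscle_set)
  base <- base[match(key, paste(base$classifier, base$muscle_set)), ]
  pos_change <- data.frame(
    classifier = pos$classifier, muscle_set = pos$muscle_set,
    change_pct = mapply(relative_improvement, base$error, pos$error)
  )
  structure(list(errors = errors, pos_change = pos_change, seed = seed),
    class = "grid_result")
}

#' Exhaustive search over training-position subsets
#'
#' For each subset size `n`, trains a classifier on data from every
#' combination of `n` wrist positions and tests it on held-out data from
#' all positions, keeping the combination with the lowest
#' position-averaged error (ties broken by the lexicographically smallest
#' position tuple, which is the enumeration order of [utils::combn()]).
#'
#' @param fm a TDAR `feature_matrix` over all positions.
#' @param n_range subset sizes to evaluate.
#' @param spec classifier (default LDA, the study's choice).
#' @param seed split seed.
#' @return A `subset_search_result` data.frame: one row per `n` with the
#'   best combination (comma-separated), its error and the number of
#'   combinations evaluated; per-combination errors in attribute
#'   `details`.
#' @export
subset_search <- function(fm, n_range = 1:13, spec = classifier_spec("LDA"),
                          seed = 1L) {
  n_pos <- length(unique(fm$meta$position))
  if (any(n_range < 1 | n_range > n_pos)) stop("n_range outside 1..", n_pos)
  sp <- split_features(fm, fold = 1L, seed = seed)
  rows <- list()
  details <- list()
  for (n in n_range) {
    combos <- utils::combn(n_pos, n)
    errs <- numeric(ncol(combos))
    for (i in seq_len(ncol(combos))) {
      keep <- sp$train$meta$position %in% combos[, i]
      keep_v <- sp$validation$meta$position %in% combos[, i]
      m <- fit_classifier(spec, fm_rows(sp$train, keep),
        fm_rows(sp$validation, keep_v))
      errs[i] <- classification_error(predict(m, sp$test), sp$test$meta$class,
        by_position = sp$test$meta$position)
    }
    best <- which.min(errs) # first minimum = lexicographically smallest
    rows[[length(rows) + 1]] <- data.frame(
      n = n, best_combination = paste(combos[, best], collapse = ","),
      error = errs[best], n_evaluated = ncol(combos)
    )
    details[[as.character(n)]] <- list(combinations = combos, errors = errs)
  }
  structure(do.call(rbind, rows),
    details = details, class = c("subset_search_result", "data.frame"))
}

#' Compare the two training paradigms
#'
#' Paradigm 1 trains one classifier on data from all wrist positions and
#' tests it on each position separately; paradigm 2 trains thirteen
#' position-specific classifiers, each tested on its own position. Both
#' report the mean of the 13 position-wise test errors.
#'
#' @param fm a `feature_matrix` over all positions.
#' @param spec classifier specification.
#' @param seed split seed.
#' @return data.frame with one row per paradigm (`error` = mean over
#'   positions) and the per-position errors as attribute
#'   `position_errors`.
#' @export
compare_paradigms <- function(fm, spec = classifier_spec("LDA"), seed = 1L) {
  positions <- sort(unique(fm$meta$position))
  sp <- split_features(fm, fold = 1L, seed = seed)
  m1 <- fit_classifier(spec, sp$train, sp$validation)
  pred1 <- predict(m1, sp$test)
  e1 <- vapply(positions, function(q) {
    rows <- sp$test$meta$position == q
    classification_error(pred1[rows], sp$test$meta$class[rows])
  }, numeric(1))
  e2 <- vapply(positions, function(q) {
    fq <- fm_rows(fm, fm$meta$position == q)
    spq <- split_features(fq, fold = 1L, seed = seed)
    mq <- fit_classifier(spec, spq$train, spq$validation)
    classification_error(predict(mq, spq$test), spq$test$meta$class)
  }, numeric(1))
  structure(
    data.frame(paradigm = c(1L, 2L), error = c(mean(e1), mean(e2))),
    position_errors = list(paradigm1 = e1, paradigm2 = e2)
  )
}
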