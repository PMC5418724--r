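#' Classifier specification
#'
#' The four classifiers compared in the study: linear and quadratic
#' discriminant analysis (LDA/QDA), and one-hidden-layer perceptrons with
#' identity (LNN, 4 hidden units) or hyperbolic-tangent (MLPANN, 7 hidden
#' units) activations, trained by scaled conjugate gradients with
#' validation-based early stopping. Inputs are z-scored with training-set
#' statistics; discriminant covariances are ridge-regularized by
#' `eps * trace(Sigma) / d` on the diagonal.
#'
#' @param kind one of `"LDA"`, `"QDA"`, `"LNN"`, `"MLPANN"`.
#' @param hidden_units hidden-layer width (ignored for LDA/QDA); defaults
#'   to 7 for MLPANN, 4 for LNN.
#' @param seed integer seed for network initialization.
#' @param restarts seeded initializations kept-best for the networks.
#' @param max_iter SCG iteration cap.
#' @param patience consecutive validation-error increases before stopping.
#' @param ridge_eps covariance regularization factor for LDA/QDA.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("LDA", "QDA", "LNN", "MLPANN"),
                            hidden_units = NULL, seed = 1L, restarts = 3L,
                            max_iter = 300L, patience = 6L, ridge_eps = 1e-6) {
  kind <- match.arg(kind)
  if (is.null(hidden_units)) {
    hidden_units <- switch(kind, MLPANN = 7L, LNN = 4L, 0L)
  }
  structure(list(
    kind = kind, hidden_units = hidden_units,
    hidden_activation = switch(kind, MLPANN = "tanh", LNN = "identity", "none"),
    trainer = "scg", seed = as.integer(seed), restarts = restarts,
    max_iter = max_iter, patience = patience, ridge_eps = ridge_eps
  ), class = "classifier_spec")
}

#' Stratified 50/20/30 train/validation/test split with two folds
#'
#' Rows are split per (class, position) cell into 50% training, 20%
#' validation and 30% testing. Fold 2 exchanges the roles of the fold-1
#' train and test partitions (it trains on the fold-1 test rows and tests
#' on the fold-1 training rows, keeping the same validation rows), so
#' every row is tested in exactly one fold.
#'
#' @param fm a `feature_matrix`.
#' @param fractions named fractions summing to 1.
#' @param fold 1 or 2.
#' @param seed integer seed controlling the (shared) cell permutations.
#' @return List of three `feature_matrix` objects: `train`, `validation`,
#'   `test`.
#' @export
split_features <- function(fm, fractions = c(train = 0.5, validation = 0.2, test = 0.3),
                           fold = 1L, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, fold %in% c(1L, 2L))
  cell <- interaction(fm$meta$class, fm$meta$position, drop = TRUE)
  tr <- va <- te <- integer(0)
  for (cl in levels(cell)) {
    rows <- which(cell == cl)
    n <- length(rows)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["validation"]] * n)
    if (n_tr < 1 || n_va < 1 || n - n_tr - n_va < 1) {
      stop("cell ", cl, " too small to stratify (", n, " rows)")
    }
    perm <- withr::with_seed(seed, rows[sample.int(n)])
    A <- perm[seq_len(n_tr)]
    B <- perm[n_tr + seq_len(n_va)]
    C <- perm[(n_tr + n_va + 1):n]
    if (fold == 1L) {
      tr <- c(tr, A); va <- c(va, B); te <- c(te, C)
    } else {
      tr <- c(tr, C); va <- c(va, B); te <- c(te, A)
    }
  }
  list(train = fm_rows(fm, tr), validation = fm_rows(fm, va), test = fm_rows(fm, te))
}

# closed-form Gaussian discriminant fit; pooled = TRUE for LDA
gauss_disc_fit <- function(X, y, classes, pooled, ridge_eps) {
  d <- ncol(X)
  K <- length(classes)
  means <- matrix(0, K, d)
  covs <- vector("list", K)
  priors <- numeric(K)
  for (k in seq_len(K)) {
    Xi <- X[y == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(Xi)
    covs[[k]] <- stats::cov(Xi)
    priors[k] <- nrow(Xi) / nrow(X)
  }
  if (pooled) {
    nk <- vapply(classes, function(cl) sum(y == cl), numeric(1))
    Sp <- Reduce(`+`, Map(function(S, n) S * (n - 1), covs, nk)) / (nrow(X) - K)
    covs <- rep(list(Sp), K)
  }
  covs <- lapply(covs, function(S) S + diag(ridge_eps * sum(diag(S)) / d, d))
  list(means = means, covs = covs, priors = priors, pooled = pooled, classes = classes)
}

gauss_disc_scores <- function(model, X) {
  K <- length(model$classes)
  n <- nrow(X)
  sc <- matrix(0, n, K)
  if (model$pooled) {
    ch <- chol(model$covs[[1]])
    Xi <- backsolve(ch, t(X), transpose = TRUE) # ch^-T X^T
    for (k in seq_len(K)) {
      mu <- backsolve(ch, model$means[k, ], transpose = TRUE)
      sc[, k] <- crossprod(Xi, mu) - 0.5 * sum(mu^2) + log(model$priors[k])
    }
  } else {
    for (k in seq_len(K)) {
      ch <- chol(model$covs[[k]])
      Xc <- sweep(X, 2, model$means[k, ])
      Z <- backsolve(ch, t(Xc), transpose = TRUE)
      sc[, k] <- -sum(log(diag(ch))) - 0.5 * colSums(Z^2) + log(model$priors[k])
    }
  }
  colnames(sc) <- model$classes
  sc
}

#' Fit a classifier on a training split
#'
#' Z-scores the inputs with training-set statistics, then fits the model
#' named by the spec: closed-form Gaussian discriminants for LDA/QDA, or an
#' SCG-trained softmax perceptron (early-stopped on the validation split)
#' for LNN/MLPANN. Deterministic given the spec's seed.
#'
#' @param spec a [classifier_spec()].
#' @param train training `feature_matrix`.
#' @param validation validation `feature_matrix` (required for the
#'   networks; ignored by LDA/QDA).
#' @return A `trained_classifier`.
#' @export
fit_classifier <- function(spec, train, validation = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- train$X
  y <- as.character(train$meta$class)
  classes <- sort(unique(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (spec$kind %in% c("LDA", "QDA")) {
    model <- gauss_disc_fit(Xs, y, classes, pooled = spec$kind == "LDA",
      ridge_eps = spec$ridge_eps)
  } else {
    if (is.null(validation)) stop(spec$kind, " requires a validation split")
    Xv <- sweep(sweep(validation$X, 2, ctr), 2, scl, `/`)
    model <- mlp_train(Xs, y, classes, hidden = spec$hidden_units,
      activation = spec$hidden_activation, Xval = Xv,
      yval = as.character(validation$meta$class), seed = spec$seed,
      restarts = spec$restarts, max_iter = spec$max_iter,
      patience = spec$patience)
  }
  structure(list(
    spec = spec, center = ctr, scale = scl, model = model, classes = classes,
    columns = train$columns
  ), class = "trained_classifier")
}

#' Predict motion classes
#'
#' @param object a `trained_classifier`.
#' @param newdata a `feature_matrix` or numeric matrix with the training
#'   column layout.
#' @param ... unused.
#' @return Character vector of class labels.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else newdata
  if (ncol(X) != length(object$center)) {
    stop("column layout does not match the training data")
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  if (object$spec$kind %in% c("LDA", "QDA")) {
    sc <- gauss_disc_scores(object$model, Xs)
    object$classes[max.col(sc, ties.method = "first")]
  } else {
    mlp_predict(object$model, Xs)
  }
}

#' Classification error percentage
#'
#' `100 * misclassified / total`. When `by_position` is supplied, the error
#' is computed in each wrist position separately and the position-wise
#' errors are averaged with equal weight (the study's reporting
#' convention).
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param by_position optional vector of position indices per row.
#' @return Error percentage in `[0, 100]`.
#' @export
classification_error <- function(pred, truth, by_position = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (is.null(by_position)) {
    return(100 * mean(pred != truth))
  }
  errs <- tapply(pred != truth, by_position, mean)
  100 * mean(errs)
}
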