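#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, the regression performance measure used for the
#' ratio-model networks.
#'
#' @param y_true observed values (at least 2, non-constant).
#' @param y_pred predicted values.
#' @return Numeric r-squared (can be negative for worse-than-mean fits).
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(y_true, y_pred) {
  if (length(y_true) < 2) stop("need at least 2 points")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true is constant; r-squared undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# per-cell (class x position) means and variances of every feature column,
# for one set of rows; returns list(mean, var), each [n_class, n_pos, p]
cell_moments <- function(X, meta, classes, n_pos) {
  p <- ncol(X)
  M <- array(NA_real_, c(length(classes), n_pos, p))
  V <- array(NA_real_, c(length(classes), n_pos, p))
  for (k in seq_along(classes)) {
    for (q in seq_len(n_pos)) {
      rows <- meta$class == classes[k] & meta$position == q
      Xi <- X[rows, , drop = FALSE]
      M[k, q, ] <- colMeans(Xi)
      V[k, q, ] <- apply(Xi, 2, stats::var)
    }
  }
  list(mean = M, var = V)
}

#' Ratio targets for the position-regression networks
#'
#' Splits the windows of each (class, position) cell into a statistics set
#' (`stats_fraction`, default 50%), a validation set (20%) and a test set
#' (30%); computes each feature's mean and variance per cell within each
#' set; and divides by the respective neutral-position value from the
#' statistics set. The statistics-set ratios are the training targets of
#' [fit_ratio_bank()]; the validation/test-set ratios are independent
#' estimates at the same 13 angle inputs used for early stopping and
#' r-squared reporting.
#'
#' Mean targets for a feature whose neutral mean magnitude is below
#' `1e-3` of its cross-position spread switch from ratio to
#' difference-from-neutral (ratios against a near-zero denominator are
#' meaningless for signed features); neutral variances are floored at
#' `1e-12` before dividing.
#'
#' @param fm a `feature_matrix` covering every (class, position) cell.
#' @param grid the [position_grid()] the session was recorded on.
#' @param stats_fraction fraction of windows used for the moment estimates
#'   that form the training targets.
#' @param seed integer seed for the cell splits.
#' @param neutral_position index of the neutral row in the grid (1).
#' @return A `ratio_targets` object: angle inputs (`angles`, 13 x 3 scaled
#'   to end range), per-split target arrays (`mean_targets`,
#'   `var_targets`: `[class, position, feature]` for `stats`,
#'   `validation`, `test`), `neutral` statistics, and the per-(class,
#'   feature) `mode` matrix (`"ratio"` or `"difference"`).
#' @export
compute_targets <- function(fm, grid, stats_fraction = 0.5, seed = 1L,
                            neutral_position = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- sort(unique(fm$meta$class))
  n_pos <- nrow(grid$positions)
  if (!all(seq_len(n_pos) %in% unique(fm$meta$position))) {
    stop("every grid position must be represented in the feature matrix")
  }
  fr <- c(train = stats_fraction, validation = 0.2, test = 1 - stats_fraction - 0.2)
  sp <- split_features(fm, fractions = fr, fold = 1L, seed = seed)
  p <- ncol(fm$X)
  moments <- list(
    stats = cell_moments(sp$train$X, sp$train$meta, classes, n_pos),
    validation = cell_moments(sp$validation$X, sp$validation$meta, classes, n_pos),
    test = cell_moments(sp$test$X, sp$test$meta, classes, n_pos)
  )
  neutral <- list(
    mean = moments$stats$mean[, neutral_position, , drop = TRUE],
    variance = pmax(moments$stats$var[, neutral_position, , drop = TRUE], 1e-12)
  )
  if (length(classes) == 1) {
    neutral <- lapply(neutral, function(v) matrix(v, 1, p))
  }
  rownames(neutral$mean) <- rownames(neutral$variance) <- classes
  # ratio vs difference mode per (class, feature)
  spread <- apply(moments$stats$mean, c(1, 3), stats::sd)
  mode <- ifelse(abs(neutral$mean) < 1e-3 * spread, "difference", "ratio")
  mk_targets <- function(M) {
    out <- array(NA_real_, dim(M))
    for (k in seq_along(classes)) {
      for (j in seq_len(p)) {
        if (mode[k, j] == "ratio") {
          out[k, , j] <- M[k, , j] / neutral$mean[k, j]
        } else {
          out[k, , j] <- M[k, , j] - neutral$mean[k, j]
        }
      }
    }
    out
  }
  mk_var_targets <- function(V) {
    out <- array(NA_real_, dim(V))
    for (k in seq_along(classes)) {
      out[k, , ] <- sweep(V[k, , , drop = FALSE][1, , ], 2, neutral$variance[k, ], `/`)
    }
    out
  }
  angles <- sweep(grid$positions, 2, grid$end_range_deg, `/`)
  structure(list(
    classes = classes, columns = fm$columns, grid = grid, angles = angles,
    mean_targets = lapply(moments, function(m) mk_targets(m$mean)),
    var_targets = lapply(moments, function(m) mk_var_targets(m$var)),
    neutral = neutral, mode = mode, muscle_set = fm$muscle_set,
    neutral_position = neutral_position
  ), class = "ratio_targets")
}

# ---- vectorized 3-3-1 network bank -----------------------------------------
# Each regressor is a network with 3 inputs (scaled wrist angles), 3 tanh
# hidden units and 1 linear output; all regressors share the same inputs, so
# the whole bank trains as one column-vectorized SCG problem with 16
# parameters per column.

bank_forward <- function(theta, X) {
  n <- nrow(X)
  R <- ncol(theta)
  W1 <- matrix(theta[1:9, ], nrow = 3) # 3 x 3R, unit-within-regressor
  A <- X %*% W1 + matrix(as.vector(theta[10:12, ]), n, 3 * R, byrow = TRUE)
  H <- tanh(A)
  w2 <- as.vector(theta[13:15, ])
  Hw <- H * matrix(w2, n, 3 * R, byrow = TRUE)
  i1 <- seq(1, 3 * R, by = 3)
  out <- Hw[, i1, drop = FALSE] + Hw[, i1 + 1, drop = FALSE] + Hw[, i1 + 2, drop = FALSE]
  out <- out + matrix(theta[16, ], n, R, byrow = TRUE)
  list(out = out, H = H, w2 = w2)
}

bank_loss_grad <- function(theta, X, Y) {
  n <- nrow(X)
  R <- ncol(theta)
  fw <- bank_forward(theta, X)
  E <- fw$out - Y
  loss <- colMeans(E^2)
  dOut <- 2 * E / n
  idx3 <- rep(seq_len(R), each = 3)
  dOutE <- dOut[, idx3, drop = FALSE]
  g <- matrix(0, 16, R)
  g[16, ] <- colSums(dOut)
  g[13:15, ] <- matrix(colSums(dOutE * fw$H), 3, R)
  dA <- dOutE * matrix(fw$w2, n, 3 * R, byrow = TRUE) * (1 - fw$H^2)
  g[10:12, ] <- matrix(colSums(dA), 3, R)
  g[1:9, ] <- matrix(crossprod(X, dA), 9, R)
  list(loss = loss, grad = g)
}

bank_loss <- function(theta, X, Y) {
  colMeans((bank_forward(theta, X)$out - Y)^2)
}

# flatten the target arrays into the bank's column order:
# moment (mean, var) slowest, then class, then feature column fastest
bank_layout <- function(targets) {
  K <- length(targets$classes)
  p <- nrow(targets$columns)
  data.frame(
    moment = rep(c("mean", "var"), each = K * p),
    class = rep(rep(targets$classes, each = p), 2),
    channel = rep(targets$columns$channel, 2 * K),
    feature = rep(targets$columns$feature, 2 * K),
    stringsAsFactors = FALSE
  )
}

bank_targets_matrix <- function(targets, split) {
  K <- length(targets$classes)
  n_pos <- nrow(targets$angles)
  p <- nrow(targets$columns)
  Ym <- matrix(aperm(targets$mean_targets[[split]], c(2, 3, 1)), n_pos, p * K)
  Yv <- matrix(aperm(targets$var_targets[[split]], c(2, 3, 1)), n_pos, p * K)
  cbind(Ym, Yv)
}

#' Fit the bank of position-regression networks
#'
#' Trains one 3-3-1 network (3 scaled wrist-angle inputs, 3 tanh hidden
#' units, linear output) per (class, channel, feature) and per moment
#' (mean, variance) on the statistics-split ratio targets, early-stopping
#' each network on its validation targets and recording its r-squared on
#' the held-out test targets. All networks are trained in lockstep by a
#' column-vectorized scaled-conjugate-gradient optimizer with `restarts`
#' seeded initializations each, keeping per-network best-validation
#' weights.
#'
#' Networks whose training targets are (near-)constant — spread below 1%
#' of the target scale, e.g. amplitude-invariant features under a purely
#' amplitude-modulated generator — are flagged uninformative: they return
#' the constant mean target and their r-squared is `NA`, and they are
#' excluded from bank-level r-squared summaries.
#'
#' @param targets a [compute_targets()] result.
#' @param seed integer seed for weight initialization.
#' @param restarts seeded initializations per network.
#' @param max_iter SCG iteration cap.
#' @param patience early-stopping patience.
#' @return A `ratio_bank`: network weights (`theta`, 16 x n matrix),
#'   per-network `info` data.frame (class, channel, feature, moment, mode,
#'   informative flag, constant, test r-squared), the angle scaling, and
#'   the neutral statistics.
#' @export
fit_ratio_bank <- function(targets, seed = 1L, restarts = 3L, max_iter = 300L,
                           patience = 6L) {
  stopifnot(inherits(targets, "ratio_targets"))
  X <- targets$angles
  info <- bank_layout(targets)
  Ytr <- bank_targets_matrix(targets, "stats")
  Yva <- bank_targets_matrix(targets, "validation")
  Yte <- bank_targets_matrix(targets, "test")
  R <- ncol(Ytr)
  K <- length(targets$classes)
  p <- nrow(targets$columns)
  info$mode <- c(as.vector(t(targets$mode)), rep("ratio", K * p))
  const <- colMeans(Ytr)
  spread <- apply(Ytr, 2, stats::sd)
  informative <- spread >= 0.01 * pmax(1, abs(const))
  info$informative <- informative
  info$constant <- const

  theta <- matrix(0, 16, R)
  r2 <- rep(NA_real_, R)
  if (any(informative)) {
    Xf <- X
    Yf <- Ytr[, informative, drop = FALSE]
    Yvf <- Yva[, informative, drop = FALSE]
    Rf <- ncol(Yf)
    fn <- function(th) bank_loss_grad(th, Xf, Yf)
    val_fn <- function(th) bank_loss(th, Xf, Yvf)
    best_theta <- NULL
    best_val <- rep(Inf, Rf)
    for (rs in seq_len(restarts)) {
      th0 <- withr::with_seed(seed + rs - 1L, matrix(runif(16 * Rf, -0.5, 0.5), 16, Rf))
      # start the output bias at the target mean so early stopping compares
      # against a sensible baseline
      th0[16, ] <- th0[16, ] * 0.1 + colMeans(Yf)
      fit <- scg_optimize(th0, fn, val_fn, max_iter = max_iter, patience = patience)
      better <- fit$val_loss < best_val
      if (is.null(best_theta)) {
        best_theta <- fit$theta
        best_val <- fit$val_loss
      } else if (any(better)) {
        best_theta[, better] <- fit$theta[, better]
        best_val[better] <- fit$val_loss[better]
      }
    }
    theta[, informative] <- best_theta
    pred_te <- bank_forward(best_theta, X)$out
    Ytef <- Yte[, informative, drop = FALSE]
    sst <- colSums(sweep(Ytef, 2, colMeans(Ytef))^2)
    ssr <- colSums((Ytef - pred_te)^2)
    r2[informative] <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)
  }
  info$r2 <- r2
  structure(list(
    theta = theta, info = info, classes = targets$classes,
    columns = targets$columns, angles = targets$angles, grid = targets$grid,
    neutral = targets$neutral, mode = targets$mode,
    muscle_set = targets$muscle_set, seed = seed
  ), class = "ratio_bank")
}

#' Predict feature mean/variance ratios at a wrist position
#'
#' Deterministic forward pass of every network in the bank at one wrist
#' position. Mean outputs are ratios relative to neutral (or differences,
#' for networks flagged `"difference"` mode); variance outputs are ratios.
#' Uninformative networks return their training-target constant.
#'
#' @param bank a [fit_ratio_bank()] result.
#' @param position a [wrist_position()] or length-3 numeric (degrees).
#' @return List with `mean` and `var` matrices (class x feature) of
#'   predicted targets, plus `mode`.
#' @export
predict_ratios <- function(bank, position) {
  theta <- as.numeric(position)
  x <- matrix(theta / bank$grid$end_range_deg, 1, 3)
  out <- bank_forward(bank$theta, x)$out[1, ]
  out[!bank$info$informative] <- bank$info$constant[!bank$info$informative]
  K <- length(bank$classes)
  p <- nrow(bank$columns)
  half <- K * p
  list(
    mean = matrix(out[seq_len(half)], K, p, byrow = TRUE,
      dimnames = list(bank$classes, NULL)),
    var = matrix(out[half + seq_len(half)], K, p, byrow = TRUE,
      dimnames = list(bank$classes, NULL)),
    mode = bank$mode
  )
}

#' Summarize bank r-squared by class (and overall)
#'
#' Mean test r-squared over informative networks, split by moment and
#' motion class.
#'
#' @param bank a `ratio_bank`.
#' @return data.frame with per-class and overall mean r-squared for the
#'   mean- and variance-ratio networks.
#' @export
bank_r2_summary <- function(bank) {
  info <- bank$info[bank$info$informative & !is.na(bank$info$r2), ]
  agg <- stats::aggregate(r2 ~ moment + class, data = info, FUN = mean)
  overall <- stats::aggregate(r2 ~ moment, data = info, FUN = mean)
  overall$class <- "(all)"
  rbind(agg, overall[, c("moment", "class", "r2")])
}

#' @export
print.ratio_bank <- function(x, ...) {
  n_inf <- sum(x$info$informative)
  cat(sprintf(
    "<ratio_bank> %d networks (%d informative) over %d classes x %d features [%s]\n",
    nrow(x$info), n_inf, length(x$classes), nrow(x$columns), x$muscle_set
  ))
  invisible(x)
}

#' Parameter recovery of the bank against the generator's ground truth
#'
#' For synthetic sessions the generator's [true_ratio()] provides the exact
#' mean/variance ratio of every amplitude-proportional feature (MAV, WL) at
#' every grid position; amplitude-invariant features (ZC, SSC, AR
#' coefficients) have a constant unit ratio, so r-squared against their
#' ground truth is undefined and they are excluded. For each network with a
#' varying ground truth this summarizes (a) its held-out test-target
#' r-squared (the study's performance measure) and (b) the r-squared of its
#' grid predictions against the exact generator ratios.
#'
#' @param bank a fitted [fit_ratio_bank()].
#' @param config the [session_config()] the session was generated with.
#' @return data.frame with one row per moment (`mean`, `var`): number of
#'   networks with varying ground truth, their average test r-squared
#'   (`r2_test`) and average r-squared against the generator truth
#'   (`r2_truth`).
#' @export
bank_recovery_summary <- function(bank, config) {
  grid <- bank$grid
  n_pos <- nrow(grid$positions)
  K <- length(bank$classes)
  p <- nrow(bank$columns)
  # exact gain ratios per (position, class, channel)
  g0 <- vapply(bank$classes, function(cl) session_gain(config, cl, c(0, 0, 0)),
    numeric(ncol(config$modulation$base_gain)))
  ratio <- array(NA_real_, c(n_pos, K, ncol(g0) * 0 + nrow(g0)))
  for (q in seq_len(n_pos)) {
    for (k in seq_len(K)) {
      ratio[q, k, ] <- session_gain(config, bank$classes[k], grid$positions[q, ]) / g0[, k]
    }
  }
  # feature scaling exponents: amplitude-linear features follow the gain
  # ratio; scale-invariant features have constant unit ratio
  expo <- ifelse(bank$columns$feature %in% c("mav", "wl"), 1, 0)
  pred <- lapply(seq_len(n_pos), function(q) predict_ratios(bank, grid$positions[q, ]))
  out <- list()
  for (mo in c("mean", "var")) {
    r2_test <- r2_truth <- c()
    for (k in seq_len(K)) {
      for (j in seq_len(p)) {
        if (expo[j] == 0) next
        tr <- ratio[, k, bank$columns$channel[j]]^(if (mo == "mean") 1 else 2)
        if (stats::sd(tr) < 1e-9) next
        pj <- vapply(pred, function(pr) pr[[mo]][k, j], numeric(1))
        r2_truth <- c(r2_truth, r_squared(tr, pj))
        ri <- bank$info$r2[bank$info$moment == (if (mo == "mean") "mean" else "var") &
          bank$info$class == bank$classes[k]][j]
        r2_test <- c(r2_test, ri)
      }
    }
    out[[mo]] <- data.frame(moment = mo, n = length(r2_truth),
      r2_test = mean(r2_test, na.rm = TRUE), r2_truth = mean(r2_truth))
  }
  do.call(rbind, out)
}
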