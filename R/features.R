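#' Time-domain EMG window features
#'
#' The four time-domain members of the TDAR feature set, computed on one
#' signal window: mean absolute value (MAV), zero-crossing count (ZC),
#' slope-sign-change count (SSC) and waveform length (WL). ZC counts
#' consecutive sample pairs of opposite sign whose difference exceeds the
#' deadzone; SSC counts interior samples whose neighbouring first
#' differences have a product exceeding the deadzone; WL is the sum of
#' absolute first differences. The deadzone defaults to 0 (pure sign
#' logic).
#'
#' @param window numeric vector of signal samples.
#' @param deadzone non-negative amplitude threshold for ZC/SSC.
#' @return A single numeric value (counts for ZC/SSC).
#' @name td_features
#' @examples
#' mav(c(1, -1, 2, -2))            # 1.5
#' zero_crossings(c(1, -1, 1, -1)) # 3
#' slope_sign_changes(c(1, 2, 1, 2, 1)) # 3
#' waveform_length(c(0, 1, 0, 1))  # 3
NULL

#' @rdname td_features
#' @export
mav <- function(window) {
  if (length(window) == 0) stop("empty window")
  mean(abs(window))
}

#' @rdname td_features
#' @export
zero_crossings <- function(window, deadzone = 0) {
  if (length(window) == 0) stop("empty window")
  if (deadzone < 0) stop("deadzone must be non-negative")
  if (length(window) < 2) return(0L)
  a <- window[-length(window)]
  b <- window[-1]
  sum(a * b < 0 & abs(a - b) > deadzone)
}

#' @rdname td_features
#' @export
slope_sign_changes <- function(window, deadzone = 0) {
  if (length(window) < 3) stop("window must have at least 3 samples")
  if (deadzone < 0) stop("deadzone must be non-negative")
  x <- window
  n <- length(x)
  mid <- x[2:(n - 1)]
  sum((mid - x[1:(n - 2)]) * (mid - x[3:n]) > deadzone)
}

#' @rdname td_features
#' @export
waveform_length <- function(window) {
  if (length(window) < 2) stop("window must have at least 2 samples")
  sum(abs(diff(window)))
}

#' Burg autoregressive coefficients of a window
#'
#' Coefficients of the order-`order` all-pole model in the prediction
#' convention `x_t = sum_k a_k x_{t-k} + e_t` (the same convention as
#' [stats::ar.burg()]), estimated by Burg's lattice recursion on the
#' mean-removed window. A zero-variance window returns all-zero
#' coefficients.
#'
#' @param window numeric vector, length well above `order`.
#' @param order model order (default 6, the TDAR choice).
#' @return Numeric vector of `order` coefficients.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 500))
#' round(ar_coefficients(x, 2), 2)
ar_coefficients <- function(window, order = 6L) {
  if (length(window) <= 2L * order) stop("window too short for AR order ", order)
  drop(burg_cols(matrix(window, ncol = 1), order))
}

# Vectorized Burg recursion: columns of W are windows; returns order x m
# coefficient matrix in the prediction convention. Mean-removed per column;
# zero-variance columns yield zero coefficients.
burg_cols <- function(W, order = 6L) {
  W <- sweep(W, 2, colMeans(W))
  n <- nrow(W)
  m <- ncol(W)
  f <- W[-1, , drop = FALSE]
  b <- W[-n, , drop = FALSE]
  A <- matrix(0, order, m)
  for (k in seq_len(order)) {
    num <- 2 * colSums(f * b)
    den <- colSums(f * f) + colSums(b * b)
    refl <- ifelse(den > 0, num / den, 0)
    if (k > 1) {
      prev <- A[1:(k - 1), , drop = FALSE]
      A[1:(k - 1), ] <- prev - rep(refl, each = k - 1) * prev[(k - 1):1, , drop = FALSE]
    }
    A[k, ] <- refl
    if (k < order) {
      nf <- nrow(f)
      fn <- f[-1, , drop = FALSE] - rep(refl, each = nf - 1) * b[-1, , drop = FALSE]
      b <- b[-nf, , drop = FALSE] - rep(refl, each = nf - 1) * f[-nf, , drop = FALSE]
      f <- fn
    }
  }
  A
}

#' Mean wrist angles of a window (POS features)
#'
#' @param gonio_window 3 x L matrix of wrist angles (degrees).
#' @return Length-3 numeric: mean flexion, deviation, rotation angle.
#' @export
pos_features <- function(gonio_window) {
  if (length(gonio_window) == 0) stop("empty window")
  rowMeans(gonio_window)
}

feature_names_tdar <- function() c("mav", "zc", "ssc", "wl", paste0("ar", 1:6))

muscle_channels <- function(groups, muscle_set) {
  switch(muscle_set,
    extrinsic = which(groups == "extrinsic"),
    intrinsic = which(groups == "intrinsic"),
    combined = seq_along(groups),
    stop("unknown muscle set: ", muscle_set)
  )
}

# all 10 TDAR features for every window of one channel, vectorized across
# windows; W is L x n_windows
tdar_cols <- function(W, deadzone = 0, ar_order = 6L) {
  L <- nrow(W)
  a <- W[-L, , drop = FALSE]
  b <- W[-1, , drop = FALSE]
  D <- b - a
  mid <- W[2:(L - 1), , drop = FALSE]
  cbind(
    mav = colMeans(abs(W)),
    zc = colSums(a * b < 0 & abs(D) > deadzone),
    ssc = colSums((mid - W[1:(L - 2), , drop = FALSE]) *
      (mid - W[3:L, , drop = FALSE]) > deadzone),
    wl = colSums(abs(D)),
    t(burg_cols(W, ar_order))
  )
}

#' Extract the TDAR (+ POS) feature matrix from a session
#'
#' Segments every trial into sliding windows and computes, per selected
#' channel, the 10 TDAR features (MAV, ZC, SSC, WL, six Burg AR
#' coefficients), optionally appending the three mean wrist angles (POS)
#' in degrees. One row per window; class/position/repetition labels are
#' carried through.
#'
#' @param session an `emg_session` (ideally filtered; see
#'   [filter_session()]).
#' @param wspec a [window_spec()].
#' @param muscle_set `"extrinsic"` (forearm channels), `"intrinsic"` (hand
#'   channels) or `"combined"`.
#' @param include_pos append POS features?
#' @param deadzone ZC/SSC deadzone amplitude.
#' @return A `feature_matrix`: list with `X` (windows x features numeric
#'   matrix), `meta` (data.frame: `class`, `position`, `rep`, `window`),
#'   `columns` (data.frame: `channel`, `feature`; POS rows have channel
#'   `NA`), `muscle_set` and `include_pos`.
#' @export
extract_features <- function(session, wspec = window_spec(),
                             muscle_set = c("combined", "extrinsic", "intrinsic"),
                             include_pos = FALSE, deadzone = 0) {
  muscle_set <- match.arg(muscle_set)
  cfg <- attr(session, "config")
  fs <- if (!is.null(cfg)) cfg$fs_hz else 1000
  chans <- muscle_channels(session[[1]]$channel_groups, muscle_set)
  fnames <- feature_names_tdar()
  blocks <- vector("list", length(session))
  metas <- vector("list", length(session))
  for (i in seq_along(session)) {
    tr <- session[[i]]
    idx <- window_index(ncol(tr$signal), fs, wspec)
    nw <- ncol(idx)
    # one L x (nw * n_chan) matrix so the Burg recursion runs once per trial
    Wall <- matrix(t(tr$signal[chans, , drop = FALSE])[as.vector(idx), ],
      nrow = nrow(idx))
    feats <- tdar_cols(Wall, deadzone)
    nf <- length(fnames)
    X <- matrix(0, nw, nf * length(chans))
    for (j in seq_along(chans)) {
      X[, ((j - 1) * nf + 1):(j * nf)] <- feats[((j - 1) * nw + 1):(j * nw), ]
    }
    if (include_pos) {
      gm <- vapply(1:3, function(d) colMeans(matrix(tr$gonio[d, idx], nrow(idx))),
        numeric(nw))
      X <- cbind(X, gm)
    }
    blocks[[i]] <- X
    metas[[i]] <- data.frame(
      class = tr$class_label, position = tr$position_index,
      rep = tr$rep_index, window = seq_len(nw)
    )
  }
  cols <- data.frame(
    channel = rep(chans, each = length(fnames)),
    feature = rep(fnames, length(chans))
  )
  if (include_pos) {
    cols <- rbind(cols, data.frame(
      channel = NA_integer_,
      feature = c("pos_flexion", "pos_deviation", "pos_rotation")
    ))
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- ifelse(is.na(cols$channel), cols$feature,
    sprintf("ch%02d_%s", cols$channel, cols$feature))
  structure(list(
    X = X, meta = do.call(rbind, metas), columns = cols,
    muscle_set = muscle_set, include_pos = include_pos
  ), class = "feature_matrix")
}

#' Subset the rows of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param rows integer or logical row index.
#' @return The subsetted `feature_matrix`.
#' @export
fm_rows <- function(fm, rows) {
  fm$X <- fm$X[rows, , drop = FALSE]
  fm$meta <- fm$meta[rows, , drop = FALSE]
  rownames(fm$meta) <- NULL
  fm
}

#' Subset the columns of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param cols integer or logical column index.
#' @return The subsetted `feature_matrix`.
#' @export
fm_cols <- function(fm, cols) {
  fm$X <- fm$X[, cols, drop = FALSE]
  fm$columns <- fm$columns[cols, , drop = FALSE]
  rownames(fm$columns) <- NULL
  fm$include_pos <- any(grepl("^pos_", fm$columns$feature))
  fm
}

#' Drop the POS columns of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @return The TDAR-only `feature_matrix`.
#' @export
fm_drop_pos <- function(fm) {
  fm_cols(fm, !grepl("^pos_", fm$columns$feature))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d windows x %d features (%s%s), %d classes x %d positions\n",
    nrow(x$X), ncol(x$X), x$muscle_set, if (x$include_pos) " + POS" else "",
    length(unique(x$meta$class)), length(unique(x$meta$position))
  ))
  invisible(x)
}
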