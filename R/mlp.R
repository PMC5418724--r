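# One-hidden-layer perceptron with softmax output and cross-entropy loss,
# trained by scaled conjugate gradients with validation-based early
# stopping. The hidden activation is tanh (MLPANN) or identity (LNN; then
# the network is mathematically a reduced linear softmax model).

mlp_pack <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

mlp_unpack <- function(theta, d, h, K) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(h * K)], h, K); i <- i + h * K
  b2 <- theta[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(theta, X, d, h, K, act) {
  w <- mlp_unpack(theta, d, h, K)
  A <- X %*% w$W1
  A <- sweep(A, 2, w$b1, `+`)
  H <- if (act == "tanh") tanh(A) else A
  Z <- H %*% w$W2
  Z <- sweep(Z, 2, w$b2, `+`)
  list(H = H, Z = Z, w = w)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# mean cross-entropy and gradient; Y is a one-hot n x K matrix
mlp_ce_grad <- function(theta, X, Y, d, h, K, act) {
  n <- nrow(X)
  fw <- mlp_forward(theta, X, d, h, K, act)
  Pr <- softmax_rows(fw$Z)
  loss <- -sum(Y * log(pmax(Pr, 1e-300))) / n
  dZ <- (Pr - Y) / n
  gW2 <- crossprod(fw$H, dZ)
  gb2 <- colSums(dZ)
  dH <- dZ %*% t(fw$w$W2)
  dA <- if (act == "tanh") dH * (1 - fw$H^2) else dH
  gW1 <- crossprod(X, dA)
  gb1 <- colSums(dA)
  list(loss = loss, grad = mlp_pack(gW1, gb1, gW2, gb2))
}

mlp_ce_loss <- function(theta, X, Y, d, h, K, act) {
  Pr <- softmax_rows(mlp_forward(theta, X, d, h, K, act)$Z)
  -sum(Y * log(pmax(Pr, 1e-300))) / nrow(X)
}

one_hot <- function(y, levels) {
  Y <- matrix(0, length(y), length(levels))
  Y[cbind(seq_along(y), match(y, levels))] <- 1
  Y
}

# Train with `restarts` seeded initializations, keeping the weights with the
# best validation loss (or training loss when no validation set is given).
mlp_train <- function(X, y, classes, hidden, activation = c("tanh", "identity"),
                      Xval = NULL, yval = NULL, seed = 1L, restarts = 3L,
                      max_iter = 300L, patience = 6L) {
  activation <- match.arg(activation)
  d <- ncol(X)
  h <- hidden
  K <- length(classes)
  Y <- one_hot(y, classes)
  fn <- function(theta) {
    r <- mlp_ce_grad(theta[, 1], X, Y, d, h, K, activation)
    list(loss = r$loss, grad = matrix(r$grad, ncol = 1))
  }
  val_fn <- NULL
  if (!is.null(Xval)) {
    Yval <- one_hot(yval, classes)
    val_fn <- function(theta) mlp_ce_loss(theta[, 1], Xval, Yval, d, h, K, activation)
  }
  P <- d * h + h + h * K + K
  best <- NULL
  for (rs in seq_len(restarts)) {
    theta0 <- withr::with_seed(seed + rs - 1L,
      matrix(runif(P, -0.5, 0.5) / sqrt(d + 1), ncol = 1))
    fit <- scg_optimize(theta0, fn, val_fn, max_iter = max_iter, patience = patience)
    score <- if (!is.null(val_fn)) fit$val_loss else fit$loss
    if (is.null(best) || score < best$score) {
      best <- list(theta = fit$theta[, 1], score = score, iterations = fit$iterations)
    }
  }
  structure(list(
    theta = best$theta, d = d, hidden = h, classes = classes,
    activation = activation, score = best$score, iterations = best$iterations
  ), class = "myowrist_mlp")
}

mlp_scores <- function(model, X) {
  fw <- mlp_forward(model$theta, X, model$d, model$hidden,
    length(model$classes), model$activation)
  softmax_rows(fw$Z)
}

mlp_predict <- function(model, X) {
  model$classes[max.col(mlp_scores(model, X), ties.method = "first")]
}
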