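# Scaled conjugate gradient optimization (Moller 1993), vectorized over the
# columns of the parameter matrix so that many small independent problems
# (e.g. one regression network per feature/class/moment) train in lockstep.
#
# fn(theta)  -> list(loss = length-R numeric, grad = P x R matrix)
# val_fn     -> optional function(theta) -> length-R validation losses, used
#               for per-column early stopping (patience rule; the weights at
#               the best validation loss are restored)
#
# Each column carries its own SCG state (raise/lower of the scale parameter,
# success flag, restart counter); columns stop independently when their
# gradient vanishes or their validation loss keeps increasing.

colscale <- function(M, v) M * rep(v, each = nrow(M))

scg_optimize <- function(theta, fn, val_fn = NULL, max_iter = 200L,
                         patience = 6L, grad_tol = 1e-8) {
  P <- nrow(theta)
  R <- ncol(theta)
  x <- theta
  ev <- fn(x)
  fold <- ev$loss
  gradnew <- ev$grad
  gradold <- gradnew
  d <- -gradnew
  success <- rep(TRUE, R)
  nsuccess <- rep(0L, R)
  beta <- rep(1, R)
  betamin <- 1e-15
  betamax <- 1e100
  sigma0 <- 1e-4
  active <- rep(TRUE, R)
  mu <- kappa <- theta2 <- rep(0, R)

  track_val <- !is.null(val_fn)
  if (track_val) {
    best_val <- val_fn(x)
    best_x <- x
    bad <- rep(0L, R)
  }

  for (j in seq_len(max_iter)) {
    upd <- active & success
    if (any(upd)) {
      mu_n <- colSums(d * gradnew)
      flip <- upd & mu_n >= 0
      if (any(flip)) {
        d[, flip] <- -gradnew[, flip]
        mu_n[flip] <- colSums(d[, flip, drop = FALSE] * gradnew[, flip, drop = FALSE])
      }
      mu[upd] <- mu_n[upd]
      kap <- colSums(d * d)
      kappa[upd] <- kap[upd]
      active <- active & !(upd & kappa < 1e-300)
      sigma <- sigma0 / sqrt(pmax(kappa, 1e-300))
      gplus <- fn(x + colscale(d, sigma))$grad
      th <- colSums(d * (gplus - gradnew)) / sigma
      theta2[upd] <- th[upd]
    }
    if (!any(active)) break

    delta <- theta2 + beta * kappa
    neg <- active & delta <= 0
    if (any(neg)) {
      delta[neg] <- beta[neg] * kappa[neg]
      beta[neg] <- beta[neg] - theta2[neg] / kappa[neg]
    }
    alpha <- -mu / pmax(delta, 1e-300)
    ev_new <- fn(x + colscale(d, ifelse(active, alpha, 0)))
    fnew <- ev_new$loss
    Delta <- 2 * (fnew - fold) / (alpha * mu)

    succ <- active & is.finite(Delta) & Delta >= 0
    success <- succ
    if (any(succ)) {
      x[, succ] <- x[, succ] + colscale(d[, succ, drop = FALSE], alpha[succ])
      fold[succ] <- fnew[succ]
      nsuccess[succ] <- nsuccess[succ] + 1L
      gradold[, succ] <- gradnew[, succ]
      gn <- fn(x)$grad
      gradnew[, succ] <- gn[, succ]
      gnorm <- colSums(gradnew * gradnew)
      active <- active & !(succ & gnorm < grad_tol^2)
    }

    lo <- active & is.finite(Delta) & Delta < 0.25
    beta[lo] <- pmin(4 * beta[lo], betamax)
    hi <- active & is.finite(Delta) & Delta > 0.75
    beta[hi] <- pmax(0.5 * beta[hi], betamin)

    restart <- active & nsuccess >= P
    if (any(restart)) {
      d[, restart] <- -gradnew[, restart]
      nsuccess[restart] <- 0L
    }
    cont <- active & success & !restart
    if (any(cont)) {
      gamma <- colSums((gradold - gradnew) * gradnew) / ifelse(mu != 0, mu, 1)
      dn <- colscale(d, gamma) - gradnew
      d[, cont] <- dn[, cont]
    }

    if (track_val && any(succ)) {
      v <- val_fn(x)
      better <- succ & v < best_val - 1e-12
      if (any(better)) {
        best_x[, better] <- x[, better]
        best_val[better] <- v[better]
        bad[better] <- 0L
      }
      worse <- succ & !better
      bad[worse] <- bad[worse] + 1L
      active[active & bad > patience] <- FALSE
    }
    if (!any(active)) break
  }

  if (track_val) {
    list(theta = best_x, loss = fold, val_loss = best_val, iterations = j)
  } else {
    list(theta = x, loss = fold, iterations = j)
  }
}
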