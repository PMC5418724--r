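# Brute-force reference implementations of the window features, written as
# plain loops so they share nothing with the package's vectorized code.

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_zc <- function(x, dz = 0) {
  n <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) > dz) n <- n + 1L
  }
  n
}

oracle_ssc <- function(x, dz = 0) {
  n <- 0L
  for (i in 2:(length(x) - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > dz) n <- n + 1L
  }
  n
}

oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

# Levinson-Durbin on a given autocovariance sequence: the theoretical AR
# coefficients (prediction convention) implied by acov[1..order+1]
# (lags 0..order).
oracle_levinson <- function(acov, order) {
  acov <- unname(acov)
  a <- numeric(0)
  e <- acov[1]
  for (k in seq_len(order)) {
    lambda <- (acov[k + 1] - sum(a * acov[k:2])) / e
    a <- c(a - lambda * rev(a), lambda)
    e <- e * (1 - lambda^2)
  }
  a
}
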