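# Session fixtures generated once per test run and cached, so several test
# files can share them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small session: quick, used for structural checks
small_session <- function() {
  cached("small_session", {
    cfg <- session_config(hold_s = 0.6, reps_per_position = 2, seed = 301L)
    list(config = cfg, session = filter_session(generate_session(cfg)))
  })
}

small_features <- function() {
  cached("small_features", {
    ss <- small_session()
    extract_features(ss$session, window_spec(), "combined", include_pos = TRUE)
  })
}

# medium session: enough repetitions/windows for distribution-level checks
medium_session <- function() {
  cached("medium_session", {
    cfg <- session_config(hold_s = 1.5, reps_per_position = 3, seed = 302L)
    list(config = cfg, session = filter_session(generate_session(cfg)))
  })
}

medium_features <- function() {
  cached("medium_features", {
    ms <- medium_session()
    extract_features(ms$session, window_spec(), "combined", include_pos = TRUE)
  })
}

# two well-separated Gaussian classes in 2-D, as a feature_matrix
gauss_fixture <- function(n = 200, sep = 6, seed = 99L, positions = 1L) {
  withr::with_seed(seed, {
    X <- rbind(
      cbind(rnorm(n, -sep / 2), rnorm(n)),
      cbind(rnorm(n, sep / 2), rnorm(n))
    )
    colnames(X) <- c("f1", "f2")
    structure(list(
      X = X,
      meta = data.frame(
        class = rep(c("a", "b"), each = n),
        position = rep_len(positions, 2 * n), rep = 1L, window = 1L
      ),
      columns = data.frame(channel = NA_integer_, feature = c("f1", "f2")),
      muscle_set = "combined", include_pos = FALSE
    ), class = "feature_matrix")
  })
}

# XOR-patterned two-class fixture: linearly inseparable, solvable by a tanh
# hidden layer
xor_fixture <- function(n_per_blob = 100, noise = 0.35, seed = 7L) {
  withr::with_seed(seed, {
    centers <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
    lab <- c("a", "a", "b", "b")
    X <- do.call(rbind, lapply(1:4, function(i) {
      cbind(rnorm(n_per_blob, centers[i, 1], noise),
        rnorm(n_per_blob, centers[i, 2], noise))
    }))
    colnames(X) <- c("f1", "f2")
    structure(list(
      X = X,
      meta = data.frame(
        class = rep(lab, each = n_per_blob),
        position = 1L, rep = 1L, window = 1L
      ),
      columns = data.frame(channel = NA_integer_, feature = c("f1", "f2")),
      muscle_set = "combined", include_pos = FALSE
    ), class = "feature_matrix")
  })
}
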