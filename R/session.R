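#' Wrist position triple
#'
#' A wrist posture in the study's three degrees of freedom, in degrees.
#' Sign conventions: flexion positive / extension negative; adduction (ulnar
#' deviation) positive / abduction negative; pronation positive / supination
#' negative. Neutral is `(0, 0, 0)`.
#'
#' @param flexion_deg,deviation_deg,rotation_deg angles in degrees.
#' @return A named numeric vector of length 3 with class `wrist_position`.
#' @export
#' @examples
#' wrist_position(30, 0, 0)   # mid-range flexion
wrist_position <- function(flexion_deg = 0, deviation_deg = 0, rotation_deg = 0) {
  ang <- c(flexion = flexion_deg, deviation = deviation_deg, rotation = rotation_deg)
  if (!all(is.finite(ang))) stop("wrist angles must be finite")
  structure(ang, class = "wrist_position")
}

#' The 13-position wrist grid
#'
#' Neutral plus mid-range and end-range postures for each of the six
#' movement directions (flexion, extension, adduction, abduction, pronation,
#' supination). Mid-range magnitudes are half the end-range magnitudes.
#' End-range defaults are typical wrist ranges of motion; they are
#' configurable because subjects' true ranges vary.
#'
#' @param end_range_deg named numeric: end-range magnitude per degree of
#'   freedom, in degrees (`flexion`, `deviation`, `rotation`).
#' @return A `position_grid`: list with `positions` (13 x 3 matrix, row 1
#'   neutral), `end_range_deg` and `mid_range_deg`.
#' @export
#' @examples
#' g <- position_grid()
#' nrow(g$positions)  # 13
position_grid <- function(end_range_deg = c(flexion = 60, deviation = 20, rotation = 80)) {
  stopifnot(all(end_range_deg > 0), all(c("flexion", "deviation", "rotation") %in%
    names(end_range_deg)))
  end <- end_range_deg[c("flexion", "deviation", "rotation")]
  mid <- end / 2
  pos <- matrix(0, 13, 3, dimnames = list(NULL, names(end)))
  labels <- "neutral"
  i <- 2L
  dir_names <- list(
    flexion = c("flexion", "extension"),
    deviation = c("adduction", "abduction"),
    rotation = c("pronation", "supination")
  )
  for (d in 1:3) {
    for (s in c(1, -1)) {
      nm <- dir_names[[d]][if (s > 0) 1 else 2]
      pos[i, d] <- s * mid[d]
      labels[i] <- paste0(nm, "_mid")
      pos[i + 1, d] <- s * end[d]
      labels[i + 1] <- paste0(nm, "_end")
      i <- i + 2L
    }
  }
  rownames(pos) <- labels
  structure(list(positions = pos, end_range_deg = end, mid_range_deg = mid),
    class = "position_grid")
}

#' Default position-modulation parameters for the synthetic generator
#'
#' Defines how each channel's EMG scale depends on wrist angle, per motion
#' class. The per-channel gain at wrist angle theta (degrees, 3-vector) is
#'
#'   gain = base_gain * (1 + s . theta + q . theta^2) + noise_floor
#'
#' with class/channel-specific slope `s` (per degree) and curvature `q`
#' (per degree squared, elementwise square of theta). Curvatures are
#' non-negative and slopes bounded so the multiplier stays positive over the
#' grid. Intrinsic (hand) channels receive half the extrinsic sensitivity,
#' reflecting the weaker position dependence of intrinsic muscle signals.
#' A per-repetition lognormal gain jitter (`rep_gain_sd`, shared-effort plus
#' per-channel components) emulates trial-to-trial contraction variability.
#'
#' @param n_channels total channel count (extrinsic first, then intrinsic).
#' @param n_extrinsic number of extrinsic (forearm) channels.
#' @param classes character vector of the four motion classes.
#' @param grid a [position_grid()], used to scale slope/curvature magnitudes.
#' @param spectral_band_hz band of the EMG carrier noise.
#' @param noise_floor amplitude (mV) of the position-independent floor.
#' @param rep_gain_sd lognormal sd of per-repetition gain jitter.
#' @param sensitivity_scale overall strength of the angle modulation
#'   (maximum fractional linear gain change at end range).
#' @param curvature_scale maximum quadratic gain contribution at end range.
#' @param class_contrast amplitude of the between-class differences in the
#'   channel activation profiles, relative to the mean active-class gain;
#'   controls how separable the grasps are.
#' @return A `modulation_params` list with `base_gain` (class x channel),
#'   `sensitivity` and `curvature` (class x channel x 3 arrays), plus the
#'   scalars above.
#' @export
modulation_params <- function(n_channels = 13, n_extrinsic = 9,
                              classes = c("rest", "open", "chuck", "key"),
                              grid = position_grid(),
                              spectral_band_hz = c(30, 350),
                              noise_floor = 0.01,
                              rep_gain_sd = 0.08,
                              sensitivity_scale = 0.8,
                              curvature_scale = 0.6,
                              class_contrast = 0.12) {
  K <- length(classes)
  ch <- seq_len(n_channels)
  base <- matrix(0, K, n_channels, dimnames = list(classes, NULL))
  # rest sits near the noise floor; active classes get distinct smooth
  # spatial activation profiles around the forearm/hand
  base[1, ] <- 2 * noise_floor
  phases <- seq(0, 2 * pi, length.out = K)[-1]
  for (k in 2:K) {
    base[k, ] <- 0.35 + class_contrast * cos(2 * pi * ch / n_channels + phases[k - 1])
  }
  end <- grid$end_range_deg
  sens <- array(0, c(K, n_channels, 3), dimnames = list(classes, NULL, names(end)))
  curv <- array(0, c(K, n_channels, 3), dimnames = list(classes, NULL, names(end)))
  for (k in seq_len(K)) {
    for (d in 1:3) {
      # smooth class- and channel-specific patterns, bounded so that
      # 1 + s*theta + q*theta^2 >= 1 - sensitivity_scale > 0 on the grid
      sens[k, , d] <- sensitivity_scale / end[d] *
        sin(2 * pi * ch / n_channels + 0.9 * k + 1.7 * d)
      curv[k, , d] <- curvature_scale / end[d]^2 *
        (0.5 + 0.5 * cos(2 * pi * ch / n_channels + 0.6 * k * d))
    }
  }
  intr <- setdiff(ch, seq_len(n_extrinsic))
  sens[, intr, ] <- sens[, intr, , drop = FALSE] * 0.5
  curv[, intr, ] <- curv[, intr, , drop = FALSE] * 0.5
  structure(list(
    base_gain = base, sensitivity = sens, curvature = curv,
    spectral_band_hz = spectral_band_hz, noise_floor = noise_floor,
    rep_gain_sd = rep_gain_sd
  ), class = "modulation_params")
}

#' Synthetic-session configuration
#'
#' Describes one recording session with the study's structure: 9 extrinsic +
#' 4 intrinsic channels at 1000 Hz, four motion classes (rest, hand open,
#' chuck grip, key grip), 3-second holds repeated 6 times in each of 13
#' wrist positions.
#'
#' @param n_channels_extrinsic,n_channels_intrinsic channel counts.
#' @param fs_hz sampling rate (Hz).
#' @param hold_s hold duration per repetition (seconds).
#' @param reps_per_position repetitions per class per position.
#' @param classes the four motion-class labels.
#' @param grid a [position_grid()].
#' @param seed integer seed; identical seeds give identical sessions.
#' @param modulation a [modulation_params()]; built from the other arguments
#'   when `NULL`.
#' @return A `session_config` list.
#' @export
session_config <- function(n_channels_extrinsic = 9, n_channels_intrinsic = 4,
                           fs_hz = 1000, hold_s = 3, reps_per_position = 6,
                           classes = c("rest", "open", "chuck", "key"),
                           grid = position_grid(), seed = 1L,
                           modulation = NULL) {
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (hold_s <= 0) stop("hold_s must be positive")
  if (reps_per_position < 1) stop("reps_per_position must be >= 1")
  if (n_channels_extrinsic + n_channels_intrinsic < 1) stop("need at least one channel")
  if (length(classes) != 4) stop("the study design uses exactly 4 motion classes")
  n_ch <- n_channels_extrinsic + n_channels_intrinsic
  if (is.null(modulation)) {
    modulation <- modulation_params(
      n_channels = n_ch, n_extrinsic = n_channels_extrinsic,
      classes = classes, grid = grid
    )
  }
  stopifnot(ncol(modulation$base_gain) == n_ch)
  structure(list(
    n_channels_extrinsic = n_channels_extrinsic,
    n_channels_intrinsic = n_channels_intrinsic,
    fs_hz = fs_hz, hold_s = hold_s, reps_per_position = reps_per_position,
    classes = classes, grid = grid, seed = as.integer(seed),
    modulation = modulation
  ), class = "session_config")
}

# analytic per-channel signal scale (std, mV) for one class at wrist angle
# theta (length-3 degrees); vectorized over channels
session_gain <- function(config, class, theta) {
  m <- config$modulation
  k <- match(class, config$classes)
  if (is.na(k)) stop("unknown class: ", class)
  mult <- 1 + m$sensitivity[k, , ] %*% theta + m$curvature[k, , ] %*% theta^2
  if (any(mult <= 0)) stop("modulation produced non-positive gain")
  as.vector(m$base_gain[k, ] * mult + m$noise_floor)
}

#' Analytic feature-scale ratio of a wrist position relative to neutral
#'
#' The generator's ground truth for parameter-recovery tests: the ratio of
#' the per-channel signal scale at `position` to the scale at neutral.
#' Features proportional to signal amplitude (MAV, WL) have this mean ratio;
#' their variances scale with its square.
#'
#' @param config a [session_config()].
#' @param class motion-class label.
#' @param channel channel index (1-based).
#' @param position a [wrist_position()] or length-3 numeric (degrees).
#' @return Named numeric `c(mean_ratio, var_ratio)`.
#' @export
#' @examples
#' cfg <- session_config()
#' true_ratio(cfg, "open", 1, wrist_position(0, 0, 0))  # c(1, 1)
true_ratio <- function(config, class, channel, position) {
  theta <- as.numeric(position)
  n_ch <- ncol(config$modulation$base_gain)
  if (channel < 1 || channel > n_ch) stop("unknown channel: ", channel)
  end <- config$grid$end_range_deg
  if (any(abs(theta) > end + 1e-9)) stop("position outside grid ranges")
  g <- session_gain(config, class, theta)[channel]
  g0 <- session_gain(config, class, c(0, 0, 0))[channel]
  c(mean_ratio = g / g0, var_ratio = (g / g0)^2)
}

# unit-variance band-limited Gaussian noise, one column per channel;
# burn-in absorbs the filter transient, scaling uses the impulse-response
# energy of the band-pass design so the output std is 1 analytically
band_noise <- function(n, n_ch, band, fs) {
  flt <- emg_bandpass(band, fs)
  burn <- 500L
  white <- matrix(rnorm((n + burn) * n_ch), n + burn, n_ch)
  out <- matrix(0, n, n_ch)
  g <- sqrt(filter_energy(flt))
  for (j in seq_len(n_ch)) {
    y <- signal::filter(flt, white[, j])
    out[, j] <- y[(burn + 1):(burn + n)] / g
  }
  out
}

# slow bounded wrist-angle jitter around a target, |jitter| <= clip_deg
gonio_jitter <- function(n, fs, sd_deg = 1.5, clip_deg = 5) {
  lp <- signal::butter(2, min(1 / (fs / 2), 0.99))
  x <- as.numeric(signal::filter(lp, rnorm(n + 1000)))[-(1:1000)]
  s <- stats::sd(x)
  if (s > 0) x <- x / s * sd_deg
  pmin(pmax(x, -clip_deg), clip_deg)
}

#' Generate a full synthetic recording session
#'
#' Produces one trial per (class, position, repetition): amplitude-modulated
#' band-limited Gaussian EMG on every channel plus a synchronized 3-channel
#' wrist-angle trace. The per-channel signal standard deviation equals the
#' analytic gain of [true_ratio()]'s model at the trial's wrist position
#' (times a small per-repetition lognormal jitter); the angle traces hold
#' the target position with bounded (<= 5 degrees) slow jitter.
#'
#' @param config a [session_config()].
#' @return List of `emg_trial` objects (length classes x positions x reps),
#'   with the config attached as attribute `config`. Each trial carries
#'   `signal` (channels x samples, mV), `gonio` (3 x samples, degrees),
#'   `class_label`, `position_index` (1 = neutral), `rep_index` and
#'   `channel_groups`.
#' @export
#' @examples
#' cfg <- session_config(hold_s = 0.5, reps_per_position = 1)
#' trials <- generate_session(cfg)
#' length(trials)  # 4 classes x 13 positions x 1 rep
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- round(config$hold_s * config$fs_hz)
  n_ch <- config$n_channels_extrinsic + config$n_channels_intrinsic
  groups <- rep(c("extrinsic", "intrinsic"),
    c(config$n_channels_extrinsic, config$n_channels_intrinsic))
  pos <- config$grid$positions
  m <- config$modulation
  trials <- vector("list", length(config$classes) * nrow(pos) * config$reps_per_position)
  i <- 0L
  withr::with_seed(config$seed, {
    for (cl in config$classes) {
      for (p in seq_len(nrow(pos))) {
        theta <- pos[p, ]
        g <- session_gain(config, cl, theta)
        for (r in seq_len(config$reps_per_position)) {
          # shared-effort + per-channel lognormal gain jitter
          jit <- exp(rnorm(1, 0, m$rep_gain_sd) + rnorm(n_ch, 0, m$rep_gain_sd)
            - m$rep_gain_sd^2)
          noise <- band_noise(n, n_ch, m$spectral_band_hz, config$fs_hz)
          sig <- t(noise) * (g * jit)
          gonio <- matrix(rep(theta, each = n), nrow = 3, byrow = TRUE)
          for (d in 1:3) gonio[d, ] <- gonio[d, ] + gonio_jitter(n, config$fs_hz)
          i <- i + 1L
          trials[[i]] <- structure(list(
            signal = sig, gonio = gonio, class_label = cl,
            position_index = p, rep_index = r, channel_groups = groups
          ), class = "emg_trial")
        }
      }
    }
  })
  structure(trials, config = config, class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<emg_session> %d trials: %d classes x %d positions x %d reps, %d ch @ %g Hz, %gs holds\n",
    length(x), length(cfg$classes), nrow(cfg$grid$positions),
    cfg$reps_per_position,
    cfg$n_channels_extrinsic + cfg$n_channels_intrinsic, cfg$fs_hz, cfg$hold_s
  ))
  invisible(x)
}
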