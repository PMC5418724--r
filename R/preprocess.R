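#' Signal-conditioning specification
#'
#' The study's conditioning chain: EMG band-pass filtered 30-350 Hz with an
#' 8th-order Chebyshev type-I digital filter, wrist-angle traces low-pass
#' filtered at 10 Hz with a 3rd-order Butterworth filter, both at 1000 Hz.
#' The Chebyshev passband ripple defaults to 0.5 dB. Filtering defaults to
#' single-pass causal application (as a real-time controller would run);
#' `zero_phase = TRUE` selects forward-backward filtering for offline
#' parity studies.
#'
#' @param emg_band_hz EMG pass band (Hz), low < high < fs/2.
#' @param emg_order overall order of the Chebyshev band-pass (even).
#' @param emg_passband_ripple_db passband ripple (dB).
#' @param gonio_cutoff_hz goniometer low-pass cutoff (Hz).
#' @param gonio_order Butterworth order.
#' @param fs_hz sampling rate (Hz).
#' @param zero_phase logical; forward-backward filtering when `TRUE`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(emg_band_hz = c(30, 350), emg_order = 8,
                        emg_passband_ripple_db = 0.5,
                        gonio_cutoff_hz = 10, gonio_order = 3,
                        fs_hz = 1000, zero_phase = FALSE) {
  if (!(emg_band_hz[1] > 0 && emg_band_hz[1] < emg_band_hz[2] &&
    emg_band_hz[2] < fs_hz / 2)) {
    stop("EMG band must satisfy 0 < low < high < fs/2")
  }
  if (gonio_cutoff_hz <= 0 || gonio_cutoff_hz >= fs_hz / 2) {
    stop("goniometer cutoff outside (0, fs/2)")
  }
  if (emg_order < 2 || emg_order %% 2 != 0) stop("emg_order must be a positive even number")
  if (gonio_order < 1) stop("gonio_order must be positive")
  structure(list(
    emg_band_hz = emg_band_hz, emg_family = "chebyshev1", emg_order = emg_order,
    emg_passband_ripple_db = emg_passband_ripple_db,
    gonio_cutoff_hz = gonio_cutoff_hz, gonio_family = "butterworth",
    gonio_order = gonio_order, fs_hz = fs_hz, zero_phase = zero_phase
  ), class = "filter_spec")
}

# Chebyshev type-I band-pass of the given *overall* order: a band-pass
# design doubles the prototype order, so the prototype order is order/2
emg_bandpass <- function(band, fs, order = 8, ripple = 0.5) {
  signal::cheby1(order / 2, ripple, band / (fs / 2), type = "pass")
}

gonio_lowpass <- function(cutoff, fs, order = 3) {
  signal::butter(order, cutoff / (fs / 2), type = "low")
}

# impulse-response energy sum(h^2) of an Arma filter (for analytic scaling
# of filtered white noise); length chosen to capture the decayed tail
filter_energy <- function(flt, n = 4096L) {
  h <- as.numeric(signal::filter(flt, c(1, rep(0, n - 1))))
  sum(h^2)
}

apply_filter <- function(flt, x, zero_phase = FALSE) {
  if (zero_phase) {
    as.numeric(signal::filtfilt(flt, x))
  } else {
    as.numeric(signal::filter(flt, x))
  }
}

#' Band-pass filter a trial's EMG channels
#'
#' Applies the spec's Chebyshev type-I band-pass to every EMG channel
#' independently; channel order and length are preserved.
#'
#' @param trial an `emg_trial` (see [generate_session()]).
#' @param spec a [filter_spec()].
#' @return The trial with filtered `signal`.
#' @export
filter_emg <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "emg_trial"), inherits(spec, "filter_spec"))
  flt <- emg_bandpass(spec$emg_band_hz, spec$fs_hz, spec$emg_order,
    spec$emg_passband_ripple_db)
  out <- trial
  for (j in seq_len(nrow(trial$signal))) {
    out$signal[j, ] <- apply_filter(flt, trial$signal[j, ], spec$zero_phase)
  }
  out
}

#' Low-pass filter wrist-angle traces
#'
#' Angle traces sit near a non-zero held position, so the filter is applied
#' to the deviation from the initial sample (avoiding the step transient a
#' zero-initialized low-pass would produce) and the offset is restored.
#'
#' @param gonio 3 x samples matrix of wrist angles (degrees), or an
#'   `emg_trial` whose `gonio` element is filtered in place.
#' @param spec a [filter_spec()].
#' @return Filtered matrix or trial, matching the input type.
#' @export
filter_gonio <- function(gonio, spec = filter_spec()) {
  flt <- gonio_lowpass(spec$gonio_cutoff_hz, spec$fs_hz, spec$gonio_order)
  lp1 <- function(x) x[1] + apply_filter(flt, x - x[1], spec$zero_phase)
  if (inherits(gonio, "emg_trial")) {
    for (d in seq_len(nrow(gonio$gonio))) {
      gonio$gonio[d, ] <- lp1(gonio$gonio[d, ])
    }
    return(gonio)
  }
  out <- gonio
  for (d in seq_len(nrow(gonio))) {
    out[d, ] <- lp1(gonio[d, ])
  }
  out
}

#' Filter every trial of a session
#'
#' Convenience wrapper applying [filter_emg()] and [filter_gonio()] to each
#' trial.
#'
#' @param session an `emg_session`.
#' @param spec a [filter_spec()].
#' @return The filtered session.
#' @export
filter_session <- function(session, spec = filter_spec()) {
  out <- lapply(session, function(tr) filter_gonio(filter_emg(tr, spec), spec))
  attributes(out) <- attributes(session)
  out
}

#' Sliding-window specification
#'
#' Analysis windows of 200 ms advanced in 20 ms frame increments, the
#' segmentation used for all feature extraction.
#'
#' @param length_ms window length (ms).
#' @param increment_ms frame increment (ms).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length_ms = 200, increment_ms = 20) {
  if (length_ms <= 0 || increment_ms <= 0) stop("window length and increment must be positive")
  if (increment_ms > length_ms) stop("increment must not exceed window length")
  structure(list(length_ms = length_ms, increment_ms = increment_ms),
    class = "window_spec")
}

# sample-index matrix (L x n_windows) for a trial of n samples
window_index <- function(n, fs, wspec) {
  L <- round(wspec$length_ms * fs / 1000)
  S <- round(wspec$increment_ms * fs / 1000)
  if (n < L) stop("trial shorter than one analysis window")
  nw <- (n - L) %/% S + 1L
  outer(seq_len(L), (seq_len(nw) - 1L) * S, `+`)
}

#' Segment a trial into analysis windows
#'
#' Windows start at multiples of the frame increment and never cross trial
#' boundaries; EMG and wrist-angle windows are time-aligned.
#'
#' @param trial an `emg_trial`.
#' @param wspec a [window_spec()].
#' @param fs_hz sampling rate (Hz).
#' @return List of windows, each with `emg` (channels x L), `gonio`
#'   (3 x L), and the trial's labels plus `window_index`.
#' @export
#' @examples
#' cfg <- session_config(hold_s = 0.5, reps_per_position = 1)
#' tr <- generate_session(cfg)[[1]]
#' length(segment_windows(tr, window_spec(), cfg$fs_hz))  # (500-200)/20+1
segment_windows <- function(trial, wspec = window_spec(), fs_hz = 1000) {
  stopifnot(inherits(trial, "emg_trial"))
  idx <- window_index(ncol(trial$signal), fs_hz, wspec)
  lapply(seq_len(ncol(idx)), function(w) {
    list(
      emg = trial$signal[, idx[, w], drop = FALSE],
      gonio = trial$gonio[, idx[, w], drop = FALSE],
      class_label = trial$class_label,
      position_index = trial$position_index,
      rep_index = trial$rep_index,
      window_index = w
    )
  })
}
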