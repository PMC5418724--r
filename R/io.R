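# Plain-text session and feature-matrix serialization: one CSV per trial
# (sample index, EMG channels, three angle channels) plus a JSON manifest
# echoing the configuration; feature matrices as CSV with a JSON sidecar.

serialize_modulation <- function(m) {
  list(
    base_gain = m$base_gain,
    sensitivity = list(data = as.vector(m$sensitivity), dim = dim(m$sensitivity)),
    curvature = list(data = as.vector(m$curvature), dim = dim(m$curvature)),
    spectral_band_hz = m$spectral_band_hz, noise_floor = m$noise_floor,
    rep_gain_sd = m$rep_gain_sd
  )
}

deserialize_modulation <- function(s, classes) {
  base <- as.matrix(s$base_gain)
  dimnames(base) <- list(classes, NULL)
  dn <- list(classes, NULL, c("flexion", "deviation", "rotation"))
  structure(list(
    base_gain = base,
    sensitivity = array(s$sensitivity$data, s$sensitivity$dim, dimnames = dn),
    curvature = array(s$curvature$data, s$curvature$dim, dimnames = dn),
    spectral_band_hz = as.numeric(s$spectral_band_hz),
    noise_floor = s$noise_floor, rep_gain_sd = s$rep_gain_sd
  ), class = "modulation_params")
}

#' Write a session to disk
#'
#' One CSV per trial (columns: `sample`, one column per EMG channel, and
#' the three wrist angles) plus `manifest.json` with labels, seed and a
#' full configuration echo. [read_session()] reverses this.
#'
#' @param session an `emg_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(session, "config")
  files <- character(length(session))
  for (i in seq_along(session)) {
    tr <- session[[i]]
    files[i] <- sprintf("trial_%03d.csv", i)
    df <- data.frame(sample = seq_len(ncol(tr$signal)))
    sig <- t(tr$signal)
    colnames(sig) <- sprintf("ch%02d", seq_len(nrow(tr$signal)))
    gon <- t(tr$gonio)
    colnames(gon) <- c("flexion", "deviation", "rotation")
    utils::write.csv(cbind(df, sig, gon), file.path(dir, files[i]),
      row.names = FALSE)
  }
  manifest <- list(
    package = "myowrist",
    seed = cfg$seed, fs_hz = cfg$fs_hz, hold_s = cfg$hold_s,
    reps_per_position = cfg$reps_per_position, classes = cfg$classes,
    n_channels_extrinsic = cfg$n_channels_extrinsic,
    n_channels_intrinsic = cfg$n_channels_intrinsic,
    end_range_deg = as.list(cfg$grid$end_range_deg),
    modulation = serialize_modulation(cfg$modulation),
    trials = data.frame(
      file = files,
      class = vapply(session, function(t) t$class_label, character(1)),
      position = vapply(session, function(t) t$position_index, integer(1)),
      rep = vapply(session, function(t) t$rep_index, integer(1))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing `manifest.json` and trial CSVs.
#' @return An `emg_session`.
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  end <- unlist(man$end_range_deg)
  cfg <- session_config(
    n_channels_extrinsic = man$n_channels_extrinsic,
    n_channels_intrinsic = man$n_channels_intrinsic,
    fs_hz = man$fs_hz, hold_s = man$hold_s,
    reps_per_position = man$reps_per_position, classes = man$classes,
    grid = position_grid(end), seed = man$seed,
    modulation = deserialize_modulation(man$modulation, man$classes)
  )
  groups <- rep(c("extrinsic", "intrinsic"),
    c(man$n_channels_extrinsic, man$n_channels_intrinsic))
  trials <- lapply(seq_len(nrow(man$trials)), function(i) {
    df <- utils::read.csv(file.path(dir, man$trials$file[i]))
    ch_cols <- grep("^ch[0-9]+$", names(df))
    structure(list(
      signal = unname(t(as.matrix(df[, ch_cols]))),
      gonio = unname(t(as.matrix(df[, c("flexion", "deviation", "rotation")]))),
      class_label = man$trials$class[i],
      position_index = as.integer(man$trials$position[i]),
      rep_index = as.integer(man$trials$rep[i]),
      channel_groups = groups
    ), class = "emg_trial")
  })
  structure(trials, config = cfg, class = "emg_session")
}

#' Write / read a feature matrix
#'
#' CSV with the label columns first and one column per feature, plus a
#' JSON sidecar (`<path>.json`) holding the column metadata, muscle set
#' and provenance.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `path` ([write_feature_matrix()]) or a `feature_matrix`
#'   ([read_feature_matrix()]).
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(cbind(fm$meta, as.data.frame(fm$X)), path, row.names = FALSE)
  jsonlite::write_json(list(
    columns = fm$columns, muscle_set = fm$muscle_set,
    include_pos = fm$include_pos,
    provenance = attr(fm, "provenance")
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  meta_cols <- c("class", "position", "rep", "window")
  X <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  structure(list(
    X = X, meta = df[, meta_cols],
    columns = as.data.frame(side$columns), muscle_set = side$muscle_set,
    include_pos = isTRUE(side$include_pos)
  ), class = "feature_matrix", provenance = side$provenance)
}

#' Serialize a fitted ratio bank to JSON
#'
#' Stores the network weights, per-network metadata (class, channel,
#' feature, moment, mode, informative flag, test r-squared), angle
#' scaling and neutral statistics; [read_ratio_bank()] reverses this.
#'
#' @param bank a `ratio_bank`.
#' @param path JSON path.
#' @return `path` / a `ratio_bank`.
#' @export
write_ratio_bank <- function(bank, path) {
  jsonlite::write_json(list(
    theta = bank$theta, info = bank$info, classes = bank$classes,
    columns = bank$columns, angles = bank$angles,
    end_range_deg = as.list(bank$grid$end_range_deg),
    neutral = list(mean = bank$neutral$mean, variance = bank$neutral$variance),
    mode = bank$mode, muscle_set = bank$muscle_set, seed = bank$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ratio_bank
#' @export
read_ratio_bank <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  neutral <- list(mean = as.matrix(s$neutral$mean),
    variance = as.matrix(s$neutral$variance))
  rownames(neutral$mean) <- rownames(neutral$variance) <- s$classes
  structure(list(
    theta = as.matrix(s$theta), info = as.data.frame(s$info),
    classes = s$classes, columns = as.data.frame(s$columns),
    angles = as.matrix(s$angles), grid = position_grid(unlist(s$end_range_deg)),
    neutral = neutral, mode = as.matrix(s$mode), muscle_set = s$muscle_set,
    seed = s$seed
  ), class = "ratio_bank")
}
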