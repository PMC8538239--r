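# Plain-text serialization of the pipeline's data types. Sampling rates
# travel in a JSON sidecar ("<path>.json") next to each CSV.

write_sidecar <- function(path, ...) {
  jsonlite::write_json(list(...), paste0(path, ".json"), auto_unbox = TRUE)
}

read_sidecar <- function(path) {
  jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
}

#' Write / read RGB traces as CSV
#'
#' Format: columns `frame, roi, r_mean, g_mean, b_mean`; frame rate in the
#' JSON sidecar.
#'
#' @param traces Named list of [rgb_trace]s.
#' @param path CSV path.
#' @return `read_rgb_traces` returns the named list of [rgb_trace]s.
#' @export
write_rgb_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(frame = seq_along(tr$r) - 1L, roi = tr$roi,
               r_mean = tr$r, g_mean = tr$g, b_mean = tr$b)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  write_sidecar(path, fps = traces[[1]]$fps)
  invisible(path)
}

#' @rdname write_rgb_traces
#' @export
read_rgb_traces <- function(path) {
  d <- utils::read.csv(path)
  fps <- read_sidecar(path)$fps
  out <- lapply(split(d, d$roi), function(g) {
    g <- g[order(g$frame), ]
    rgb_trace(g$roi[1], g$r_mean, g$g_mean, g$b_mean, fps)
  })
  out[c("nose", "left_cheek", "right_cheek")]
}

#' Write / read a trajectory bank as CSV
#'
#' Format: one row per point with columns `point_id, region`, then a column
#' pair `x_<f>, y_<f>` per frame; frame rate in the JSON sidecar.
#'
#' @param traj A [trajectory_bank].
#' @param path CSV path.
#' @return `read_trajectories` returns the [trajectory_bank].
#' @export
write_trajectories <- function(traj, path) {
  n <- traj$n_frames
  m <- matrix(NA_real_, traj$n_points, 2L * n)
  m[, seq(1L, 2L * n, by = 2L)] <- traj$xs
  m[, seq(2L, 2L * n, by = 2L)] <- traj$ys
  colnames(m) <- paste0(rep(c("x_", "y_"), n), rep(seq_len(n), each = 2L))
  d <- data.frame(point_id = seq_len(traj$n_points),
                  region = if (is.null(traj$region)) "" else traj$region)
  utils::write.csv(cbind(d, m), path, row.names = FALSE)
  write_sidecar(path, fps = traj$fps)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path)
  fps <- read_sidecar(path)$fps
  m <- as.matrix(d[, -(1:2)])
  n <- ncol(m) / 2L
  trajectory_bank(m[, seq(1L, 2L * n, by = 2L), drop = FALSE],
                  m[, seq(2L, 2L * n, by = 2L), drop = FALSE],
                  fps,
                  region = if (all(d$region == "")) NULL else d$region)
}

#' Write / read a scalar signal as CSV
#'
#' Format: columns `t_seconds, value`; sampling rate in the JSON sidecar.
#'
#' @param s A [signal1d].
#' @param path CSV path.
#' @return `read_signal` returns the [signal1d].
#' @export
write_signal <- function(s, path) {
  utils::write.csv(data.frame(t_seconds = (seq_along(s$samples) - 1) / s$fs,
                              value = s$samples),
                   path, row.names = FALSE)
  write_sidecar(path, fs = s$fs)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  d <- utils::read.csv(path)
  signal1d(d$value, read_sidecar(path)$fs)
}

#' Write / read heart-rate series as CSV
#'
#' Format: columns `t_seconds, hr_bpm, method`.
#'
#' @param hr An [hr_series] (or the stacked `hr` table of an `hr_fusion`).
#' @param path CSV path.
#' @return `read_hr_series` returns an [hr_series].
#' @export
write_hr_series <- function(hr, path) {
  utils::write.csv(data.frame(t_seconds = hr$time, hr_bpm = hr$bpm,
                              method = hr$method),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hr_series
#' @export
read_hr_series <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(time = d$t_seconds, bpm = d$hr_bpm,
                       method = d$method),
            class = c("hr_series", "data.frame"))
}

#' Export agreement metrics as JSON
#' @param stats An [agreement] result.
#' @param path Output JSON path.
#' @export
write_agreement_json <- function(stats, path) {
  jsonlite::write_json(stats[c("mae", "sdae", "rmse", "cc", "bias",
                               "loa_low", "loa_high", "n")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export Bland-Altman pairs as CSV
#' @param stats An [agreement] result.
#' @param path Output CSV path.
#' @export
write_bland_altman <- function(stats, path) {
  utils::write.csv(stats$pairs[, c("mean", "diff")], path, row.names = FALSE)
  invisible(path)
}
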