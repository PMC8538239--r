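# Motion-based pulse extraction: vertical trajectories of the 80 facial
# points are mean-centered, band-passed, amplitude-corrected (2-sigma rule),
# pruned by spectral SNR, and decomposed by PCA; the highest-SNR score
# series is the ballistocardiographic pulse signal.

#' Bank of tracked-point trajectories
#' @param xs,ys Matrices `[n_points x n_frames]` of pixel coordinates.
#' @param fps Frame rate in Hz.
#' @param region Optional per-point region labels.
#' @return Object of class `trajectory_bank`.
#' @export
trajectory_bank <- function(xs, ys, fps, region = NULL) {
  xs <- as.matrix(xs); ys <- as.matrix(ys)
  if (!all(dim(xs) == dim(ys))) stop("trajectory_bank: xs/ys shape mismatch")
  if (fps <= 0) stop("trajectory_bank: fps must be positive")
  if (!all(is.finite(xs)) || !all(is.finite(ys))) {
    stop("trajectory_bank: coordinates must be finite (no missing frames)")
  }
  structure(list(n_points = nrow(xs), n_frames = ncol(xs),
                 xs = xs, ys = ys, fps = fps, region = region),
            class = "trajectory_bank")
}

#' @export
print.trajectory_bank <- function(x, ...) {
  cat(sprintf("<trajectory_bank> %d points x %d frames @ %g Hz\n",
              x$n_points, x$n_frames, x$fps))
  invisible(x)
}

#' Bank of parallel scalar signals
#' @param channels Matrix `[n_channels x n_samples]`, all finite.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Optional identifiers (point ids).
#' @return Object of class `signal_bank`.
#' @export
signal_bank <- function(channels, fs, channel_ids = NULL) {
  channels <- as.matrix(channels)
  if (nrow(channels) < 1L) stop("signal_bank: need at least one channel")
  if (!all(is.finite(channels))) stop("signal_bank: non-finite samples")
  if (fs <= 0) stop("signal_bank: fs must be positive")
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(channels))
  structure(list(channels = channels, fs = fs, channel_ids = channel_ids),
            class = "signal_bank")
}

#' @export
print.signal_bank <- function(x, ...) {
  cat(sprintf("<signal_bank> %d channels x %d samples @ %g Hz\n",
              nrow(x$channels), ncol(x$channels), x$fs))
  invisible(x)
}

#' Vertical-motion signal bank from tracked trajectories
#'
#' Heartbeat-driven head motion is vertical, so each point's y-coordinate
#' series becomes one channel, mean-centered so its unit matches the
#' (centered) color signals. The x-coordinates are used only for the
#' tracking re-detection rule, not for pulse extraction.
#'
#' @param traj A [trajectory_bank] with at least 64 frames.
#' @return A [signal_bank] of centered y-signals.
#' @export
y_signal_bank <- function(traj) {
  stopifnot(inherits(traj, "trajectory_bank"))
  if (traj$n_frames < 64L) stop("y_signal_bank: need at least 64 frames")
  ys <- traj$ys - rowMeans(traj$ys)
  signal_bank(ys, traj$fps, channel_ids = seq_len(traj$n_points))
}

#' Band-pass and amplitude-correct every channel
#'
#' Per channel: zero-phase Butterworth band-pass (default 0.75--2.5 Hz,
#' order 2), then the 2-sigma amplitude correction ([clip_to_mean]) that
#' suppresses voluntary head-movement transients.
#'
#' @param bank A [signal_bank].
#' @param f_lo,f_hi,order Band-pass parameters (see [bandpass]).
#' @param k Amplitude-correction threshold in standard deviations.
#' @return Conditioned [signal_bank].
#' @export
condition_bank <- function(bank, f_lo = 0.75, f_hi = 2.5, order = 2L, k = 2) {
  stopifnot(inherits(bank, "signal_bank"))
  ch <- t(apply(bank$channels, 1L, function(row) {
    if (stats::sd(row) == 0) return(rep(0, length(row)))
    s <- bandpass(signal1d(row, bank$fs), f_lo, f_hi, order)
    clip_to_mean(s, k)$samples
  }))
  signal_bank(ch, bank$fs, bank$channel_ids)
}

#' Drop channels with below-average spectral SNR
#'
#' Facial expressions corrupt the points over the moving muscles; channels
#' whose SNR falls below the mean SNR across channels are removed. At least
#' one channel (the best) always survives.
#'
#' @param bank A [signal_bank] with at least 2 channels.
#' @param band Analysis band for SNR, default `c(0.75, 2.5)` Hz.
#' @return Pruned [signal_bank].
#' @export
prune_by_snr <- function(bank, band = c(0.75, 2.5)) {
  stopifnot(inherits(bank, "signal_bank"))
  if (nrow(bank$channels) < 2L) stop("prune_by_snr: need >= 2 channels")
  snrs <- apply(bank$channels, 1L, snr_of, fs = bank$fs, band = band)
  snrs[snrs == -Inf] <- 0  # degenerate (constant) channels carry no signal
  keep <- if (any(is.infinite(snrs))) is.infinite(snrs)
          else snrs >= mean(snrs)
  if (!any(keep)) keep[which.max(snrs)] <- TRUE
  signal_bank(bank$channels[keep, , drop = FALSE], bank$fs,
              bank$channel_ids[keep])
}

#' Ballistocardiographic signal from a conditioned bank
#'
#' PCA over the channels: the first `min(5, n_channels)` principal-component
#' score series are computed and the one with the highest spectral SNR is
#' returned, normalized to unit standard deviation.
#'
#' @param bank A [signal_bank].
#' @param band Analysis band for SNR selection.
#' @param n_comp Maximum number of components to consider (default 5).
#' @return A unit-variance [signal1d]: the RBCG pulse signal.
#' @export
bcg_signal <- function(bank, band = c(0.75, 2.5), n_comp = 5L) {
  stopifnot(inherits(bank, "signal_bank"))
  X <- t(bank$channels)  # samples x channels
  if (ncol(X) == 1L) {
    out <- X[, 1] - mean(X[, 1])
    return(signal1d(out / stats::sd(out), bank$fs))
  }
  scores <- pca_scores(X, min(n_comp, ncol(X)))
  j <- select_by_snr(scores, bank$fs, band)
  out <- scores[, j]
  signal1d(out / stats::sd(out), bank$fs)
}
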