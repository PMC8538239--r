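# Color-based pulse extraction: per-ROI mean-RGB traces, melanin-mean
# normalization, projection onto the pulse blood-volume (PBV) direction,
# band-pass filtering, then ICA across the three skin regions with
# SNR-based component selection.

#' Per-ROI mean RGB trace
#' @param roi Region label: `"nose"`, `"left_cheek"`, or `"right_cheek"`.
#' @param r,g,b Numeric vectors of per-frame spatial channel means
#'   (8-bit scale, 0--255), equal lengths.
#' @param fps Frame rate in Hz.
#' @return Object of class `rgb_trace`.
#' @export
rgb_trace <- function(roi, r, g, b, fps) {
  roi <- match.arg(roi, c("nose", "left_cheek", "right_cheek"))
  if (!(length(r) == length(g) && length(g) == length(b))) {
    stop("rgb_trace: channel lengths differ")
  }
  vals <- c(r, g, b)
  if (any(vals < 0 | vals > 255)) stop("rgb_trace: values outside [0, 255]")
  if (fps <= 0) stop("rgb_trace: fps must be positive")
  structure(list(roi = roi, r = as.numeric(r), g = as.numeric(g),
                 b = as.numeric(b), fps = fps),
            class = "rgb_trace")
}

#' Default pulse blood-volume direction
#'
#' The characteristic direction in RGB space along which pulse-induced color
#' change occurs for RGB cameras viewing skin, normalized to unit length.
#' The green component dominates because blood-volume pulsation is most
#' visible around 510--560 nm.
#'
#' @param weights Raw (R, G, B) weights; default `c(0.33, 0.77, 0.53)`.
#' @return Unit-norm numeric vector of length 3.
#' @export
default_pbv <- function(weights = c(0.33, 0.77, 0.53)) {
  stopifnot(length(weights) == 3L, all(is.finite(weights)))
  w <- weights / sqrt(sum(weights^2))
  if (!(w[2] >= w[1] && w[2] >= w[3])) {
    warning("default_pbv: green component is not the largest")
  }
  w
}

# Mean RGB over a half-open rect of one frame; rect clipped to the frame.
roi_channel_means <- function(frame, rect) {
  nr <- nrow(frame); nc <- ncol(frame)
  x0 <- max(0L, round_half_away(rect$x0)); x1 <- min(nc, round_half_away(rect$x1))
  y0 <- max(0L, round_half_away(rect$y0)); y1 <- min(nr, round_half_away(rect$y1))
  if (x1 <= x0 || y1 <= y0) {
    stop("extract_rgb_traces: ROI does not intersect the frame")
  }
  if (rect$x0 < 0 || rect$y0 < 0 || rect$x1 > nc || rect$y1 > nr) {
    warning("extract_rgb_traces: ROI clipped to frame bounds")
  }
  rows <- (y0 + 1L):y1; cols <- (x0 + 1L):x1
  c(mean(frame[rows, cols, 1]), mean(frame[rows, cols, 2]),
    mean(frame[rows, cols, 3]))
}

#' Spatial mean RGB traces over the skin regions
#'
#' For each frame and each of the nose / left-cheek / right-cheek regions,
#' averages every pixel channel over the region, producing the three raw
#' RGB traces that feed pulse extraction.
#'
#' @param frames List of RGB arrays `[height, width, 3]` (0--255), or a
#'   clip object with a `$frame(i)` accessor and `$n_frames`.
#' @param rois Per-frame list of ROI sets as returned by [compute_rois]
#'   (one element per frame), or a single ROI set reused for all frames.
#' @param fps Frame rate in Hz.
#' @return List of three [rgb_trace]s named nose, left_cheek, right_cheek.
#' @export
extract_rgb_traces <- function(frames, rois, fps) {
  get_frame <- if (is.list(frames) && is.function(frames$frame)) {
    frames$frame
  } else {
    function(i) frames[[i]]
  }
  n <- if (is.list(frames) && !is.null(frames$n_frames)) frames$n_frames
       else length(frames)
  per_frame <- !inherits(rois[[1]], "roi_rect") && is.null(rois[[1]]$name)
  labs <- c("nose", "left_cheek", "right_cheek")
  vals <- array(NA_real_, c(n, 3L, 3L))  # frame x roi x channel
  for (i in seq_len(n)) {
    fr <- get_frame(i)
    rs <- if (per_frame) rois[[i]] else rois
    for (j in seq_along(labs)) {
      vals[i, j, ] <- roi_channel_means(fr, rs[[labs[j]]])
    }
  }
  out <- lapply(seq_along(labs), function(j) {
    rgb_trace(labs[j], vals[, j, 1], vals[, j, 2], vals[, j, 3], fps)
  })
  names(out) <- labs
  out
}

#' Project an RGB trace onto the pulse blood-volume direction
#'
#' Channels are mean-centered (removing the melanin/skin-tone component) and
#' combined with the weight vector `w` solving `Q w = pbv`, where `Q` is the
#' 3x3 covariance of the centered channels, scaled so that `t(w) %*% pbv = 1`
#' (unit alignment with the pulse direction). This suppresses the dominant
#' distortions (e.g. common illumination) while preserving the pulse. A
#' singular covariance falls back to direct projection onto `pbv`.
#'
#' @param trace An [rgb_trace] with at least 64 frames.
#' @param pbv Unit-norm pulse direction, default [default_pbv()].
#' @return A [signal1d] pulse candidate for this region.
#' @export
pbv_project <- function(trace, pbv = default_pbv()) {
  stopifnot(inherits(trace, "rgb_trace"))
  C <- cbind(trace$r, trace$g, trace$b)
  if (nrow(C) < 64L) stop("pbv_project: need at least 64 frames")
  C <- scale(C, center = TRUE, scale = FALSE)
  Q <- stats::cov(C)
  w <- tryCatch({
    if (rcond(Q) < 1e-12) stop("singular")
    wi <- solve(Q, pbv)
    wi / as.numeric(crossprod(pbv, wi))
  }, error = function(e) {
    warning("pbv_project: singular channel covariance; projecting onto pbv")
    pbv
  })
  signal1d(as.numeric(C %*% w), trace$fps)
}

#' Photoplethysmographic signal from the three skin regions
#'
#' Applies ICA to the three band-passed per-region pulse candidates and
#' returns the component with the highest spectral SNR, normalized to unit
#' standard deviation. If ICA does not converge the decomposition falls back
#' to PCA with a warning. Near-ties in SNR (< 1e-9) resolve toward the lower
#' dominant frequency.
#'
#' @param roi_signals List of three [signal1d]s (already band-passed), equal
#'   length and sampling rate.
#' @param band Analysis band for SNR selection, default `c(0.75, 2.5)` Hz.
#' @param seed Seed for the deterministic ICA initialization.
#' @return A unit-variance [signal1d]: the RPPG pulse signal.
#' @export
ppg_signal <- function(roi_signals, band = c(0.75, 2.5), seed = 42L) {
  stopifnot(length(roi_signals) == 3L)
  fs <- roi_signals[[1]]$fs
  lens <- vapply(roi_signals, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L ||
      any(vapply(roi_signals, `[[`, numeric(1), "fs") != fs)) {
    stop("ppg_signal: inputs must share length and sampling rate")
  }
  X <- do.call(cbind, lapply(roi_signals, `[[`, "samples"))
  comps <- tryCatch({
    res <- fast_ica(X, n_comp = 3L, seed = seed)
    if (!res$converged) stop("ICA did not converge")
    res$S
  }, error = function(e) {
    warning("ppg_signal: ICA unavailable (", conditionMessage(e),
            "); falling back to PCA")
    pca_scores(X, 3L)
  })
  j <- select_by_snr(comps, fs, band)
  out <- comps[, j]
  signal1d(out / stats::sd(out), fs)
}
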