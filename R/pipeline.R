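# Windowed heart-rate estimation, agreement metrics against a reference
# series (MAE, SDAE, RMSE, Pearson CC, Bland-Altman limits of agreement),
# and the end-to-end orchestration from traces or a rendered clip to fused
# heart-rate series.

#' Heart-rate series container
#' @param time Timestamps in seconds, strictly increasing.
#' @param bpm Heart-rate estimates in beats per minute.
#' @param method Method label (`"RPPG"`, `"RBCG"`, `"EA"`, `"PCA"`,
#'   `"ICA"`, or `"REF"`).
#' @return Data frame of class `hr_series`.
#' @export
hr_series <- function(time, bpm, method) {
  if (length(time) != length(bpm)) stop("hr_series: length mismatch")
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("hr_series: times must be strictly increasing")
  }
  structure(data.frame(time = time, bpm = bpm,
                       method = rep(method, length(time))),
            class = c("hr_series", "data.frame"))
}

#' Sliding-window heart-rate estimation
#'
#' Applies [dominant_hr] to each sliding window of the signal; the estimate
#' is stamped with the window's end time. A signal shorter than one window
#' yields a single whole-signal estimate with a warning.
#'
#' @param s A [signal1d].
#' @param window_s Window length in seconds (default 30).
#' @param stride_s Stride between windows in seconds (default 1).
#' @param method Label recorded in the output.
#' @param band Analysis band in Hz.
#' @return An [hr_series].
#' @export
windowed_hr <- function(s, window_s = 30, stride_s = 1, method = "RPPG",
                        band = c(0.75, 2.5)) {
  stopifnot(inherits(s, "signal1d"))
  n <- length(s$samples)
  wn <- round(window_s * s$fs)
  if (n < wn) {
    warning("windowed_hr: signal shorter than the window; single estimate")
    est <- dominant_hr(s, band)
    return(hr_series(n / s$fs, est$bpm, method))
  }
  step <- max(1L, round(stride_s * s$fs))
  starts <- seq(1L, n - wn + 1L, by = step)
  bpm <- vapply(starts, function(i) {
    dominant_hr(signal1d(s$samples[i:(i + wn - 1L)], s$fs), band)$bpm
  }, numeric(1))
  hr_series((starts + wn - 1L) / s$fs, bpm, method)
}

#' Window-averaged reference series
#'
#' A window-end-stamped spectral estimate measures the average heart rate
#' over its window, so the matching reference at timestamp `t` is the
#' ground-truth mean over `[t - window_s, t]`. Use this to evaluate
#' [windowed_hr] output against a ground-truth trajectory.
#'
#' @param truth Data frame with columns `time` and `bpm` (e.g.
#'   [ground_truth] output).
#' @param times Window-end timestamps of the estimates.
#' @param window_s Window length used for the estimates.
#' @return An [hr_series] with method `"REF"`.
#' @export
windowed_reference <- function(truth, times, window_s = 30) {
  bpm <- vapply(times, function(tt) {
    sel <- truth$time >= tt - window_s & truth$time <= tt
    mean(truth$bpm[sel])
  }, numeric(1))
  hr_series(times, bpm, "REF")
}

#' Agreement between estimated and reference heart rates
#'
#' Pairs estimates with the nearest reference sample (within `tol_s`
#' seconds; unmatched estimates are dropped and counted) and computes mean
#' absolute error, the standard deviation of the absolute errors, root mean
#' squared error, Pearson correlation, and the Bland-Altman bias with 95%
#' limits of agreement (`bias +/- 1.96 * sd(differences)`). Differences are
#' `estimate - reference`. When either series has zero variance the
#' correlation is reported as `NA` (undefined) rather than fabricated.
#'
#' @param est,ref [hr_series] (any data frame with `time` and `bpm` works).
#' @param tol_s Matching tolerance in seconds (default 0.5).
#' @return Object of class `agreement_stats` with fields `mae`, `sdae`,
#'   `rmse`, `cc`, `bias`, `loa_low`, `loa_high`, `n`, `dropped`, and the
#'   matched `pairs` data frame.
#' @export
agreement <- function(est, ref, tol_s = 0.5) {
  idx <- vapply(est$time, function(tt) {
    d <- abs(ref$time - tt)
    j <- which.min(d)
    if (d[j] <= tol_s) j else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(sprintf("agreement: %d unmatched estimate(s) dropped", dropped))
  }
  e <- est$bpm[ok]; r <- ref$bpm[idx[ok]]
  if (length(e) < 2L) stop("agreement: fewer than 2 matched pairs")
  d <- e - r
  a <- abs(d)
  cc <- if (stats::sd(e) == 0 || stats::sd(r) == 0) NA_real_
        else stats::cor(e, r)
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mae = mean(a), sdae = stats::sd(a),
                 rmse = sqrt(mean(d^2)), cc = cc, bias = bias,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(e), dropped = dropped,
                 pairs = data.frame(est = e, ref = r,
                                    mean = (e + r) / 2, diff = d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Agreement over %d pairs:\n  MAE %.3f  SDAE %.3f  RMSE %.3f bpm\n",
    x$n, x$mae, x$sdae, x$rmse))
  cat(sprintf("  CC %s\n",
              if (is.na(x$cc)) "undefined" else sprintf("%.3f", x$cc)))
  cat(sprintf("  bias %.3f bpm, 95%% LOA [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot of an agreement analysis
#' @param x An [agreement] result.
#' @param ... Passed to [graphics::plot].
#' @export
plot.agreement_stats <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$diff,
                 xlab = "Mean of estimate and reference (bpm)",
                 ylab = "Estimate - reference (bpm)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}

# ---- End-to-end orchestration ----------------------------------------------

# Per-window extraction and fusion: slice the band-passed ROI signals and
# the conditioned, pruned trajectory bank, re-run component extraction,
# selection, and fusion inside each window, and estimate one HR per window
# per method. Component selection by spectral SNR is only informative when
# the heart rate is near-constant within the analyzed stretch, so for
# time-varying rates it must run per window (as an online system would).
# Channel pruning, by contrast, stays global: a channel's artifact
# susceptibility is a property of its facial location (which muscles move
# under it), so the whole recording gives the most reliable SNR screening
# -- window-local SNR estimates are too noisy to prune on.
windowed_pipeline_hr <- function(roi_sig, bank, methods, window_s, stride_s,
                                 band, seed) {
  fs <- bank$fs
  n <- ncol(bank$channels)
  wn <- round(window_s * fs)
  step <- max(1L, round(stride_s * fs))
  starts <- seq(1L, n - wn + 1L, by = step)
  warn_msgs <- character(0)
  est <- lapply(starts, function(i) {
    idx <- i:(i + wn - 1L)
    withCallingHandlers({
      roi_w <- lapply(roi_sig, function(s) signal1d(s$samples[idx], fs))
      rppg_w <- ppg_signal(roi_w, band = band, seed = seed)
      bank_w <- signal_bank(bank$channels[, idx, drop = FALSE], fs,
                            bank$channel_ids)
      rbcg_w <- bcg_signal(bank_w, band = band)
      rppg_z <- standardize(rppg_w)
      rbcg_z <- standardize(rbcg_w)
      if (stats::cor(rppg_z$samples, rbcg_z$samples) < 0) {
        rbcg_z <- signal1d(-rbcg_z$samples, fs)
      }
      out <- c(RPPG = dominant_hr(rppg_w, band)$bpm,
               RBCG = dominant_hr(rbcg_w, band)$bpm)
      for (m in methods) {
        f <- fuse(rppg_z, rbcg_z, m, band = band, seed = seed)
        out[m] <- dominant_hr(f, band)$bpm
      }
      out
    }, warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  })
  for (msg in unique(warn_msgs)) {
    warning("run_pipeline (in ", sum(warn_msgs == msg), " window(s)): ", msg)
  }
  bpm <- do.call(rbind, est)
  times <- (starts + wn - 1L) / fs
  series <- lapply(colnames(bpm), function(m) hr_series(times, bpm[, m], m))
  hr <- do.call(rbind, series)
  class(hr) <- c("hr_series", "data.frame")
  hr
}

# Track the clip: derive ROIs and the grid on frame 1 from the supplied
# box, carry points with pyramidal LK, maintain ROIs with the similarity
# transform, and re-derive on the >10 px rule. Returns per-frame ROI sets
# and the trajectory bank.
track_clip <- function(clip) {
  n <- clip$n_frames
  box1 <- clip$boxes[1L, ]
  face <- face_box(box1$x, box1$y, box1$w, box1$h, 0L)
  window <- max(3, round(max(face$w, face$h) / 10))
  rois <- compute_rois(face)
  grid <- make_point_grid(rois$forehead, rois$nose)
  np <- nrow(grid$points)
  xs <- matrix(NA_real_, np, n); ys <- matrix(NA_real_, np, n)
  xs[, 1] <- grid$points[, 1]; ys[, 1] <- grid$points[, 2]
  roi_list <- vector("list", n)
  roi_list[[1L]] <- rois
  resets <- integer(0)
  prev <- build_pyramid(to_gray(clip$frame(1L)), 3L)
  for (i in 2:n) {
    cur <- build_pyramid(to_gray(clip$frame(i)), 3L)
    tr <- suppressWarnings(track_pyramids(prev, cur, grid, window))
    if (tr$redetect) {
      b <- clip$boxes[i, ]
      face <- face_box(b$x, b$y, b$w, b$h, i - 1L)
      rois <- compute_rois(face)
      grid <- make_point_grid(rois$forehead, rois$nose)
      resets <- c(resets, i)
    } else {
      st <- estimate_similarity(grid$points, tr$points$points)
      rois <- lapply(rois, function(r) apply_transform(st, r))
      grid <- tr$points
    }
    xs[, i] <- grid$points[, 1]; ys[, i] <- grid$points[, 2]
    roi_list[[i]] <- rois
    prev <- cur
  }
  list(traj = trajectory_bank(xs, ys, clip$fps, region = grid$region),
       rois = roi_list, resets = resets)
}

#' Run the full fusion pipeline
#'
#' From a trace bundle (RGB traces plus a trajectory bank) or a rendered
#' clip: extracts the RPPG signal (per-region PBV projection, band-pass, ICA
#' with SNR selection), the RBCG signal (centered y-signals, band-pass,
#' 2-sigma correction, SNR pruning, PCA with SNR selection), standardizes
#' both, fuses them with the requested method(s), and estimates windowed
#' heart-rate series for RPPG, RBCG, and each fused signal. Before fusion,
#' the RBCG sign is aligned to RPPG by correlation (component signs from
#' blind source separation are arbitrary).
#'
#' The heart-rate table is computed by re-running extraction, component
#' selection, and fusion inside each sliding window, as an online system
#' would: spectral-SNR component selection is only informative when the
#' heart rate is near-constant over the stretch it sees, so a time-varying
#' rate demands per-window selection. Channel pruning stays global, since a
#' channel's artifact susceptibility is fixed by its facial location and
#' window-local SNR estimates are too noisy to screen on. The returned `signals` are the
#' whole-recording extractions, kept for inspection and plotting.
#'
#' @param input Either a list with elements `traces` (three [rgb_trace]s)
#'   and `traj` (a [trajectory_bank]), or a `synthetic_clip` from
#'   [render_clip] (processed through detection-free tracking using its
#'   first-frame face box).
#' @param method Fusion method(s): subset of `c("EA", "PCA", "ICA")`.
#' @param window_s,stride_s Windowing parameters for [windowed_hr].
#' @param band Analysis band in Hz.
#' @param pbv Pulse blood-volume direction.
#' @param seed Seed for the deterministic ICA initialization.
#' @return Object of class `hr_fusion`: `hr` (stacked [hr_series] for RPPG,
#'   RBCG and each fusion method), `signals` (the pulse signals), `resets`
#'   (re-detection frames, video path only), and the call.
#' @export
run_pipeline <- function(input, method = "EA", window_s = 30, stride_s = 1,
                         band = c(0.75, 2.5), pbv = default_pbv(),
                         seed = 42L) {
  methods <- vapply(method, fusion_method, character(1))
  if (inherits(input, "synthetic_clip")) {
    tracked <- track_clip(input)
    traces <- extract_rgb_traces(input, tracked$rois, input$fps)
    traj <- tracked$traj
    resets <- tracked$resets
  } else if (is.list(input) && !is.null(input$traces) && !is.null(input$traj)) {
    traces <- input$traces
    traj <- input$traj
    resets <- integer(0)
  } else {
    stop("run_pipeline: input must be a synthetic_clip or a trace bundle")
  }
  roi_sig <- lapply(traces[c("nose", "left_cheek", "right_cheek")],
                    function(tr) bandpass(pbv_project(tr, pbv),
                                          band[1], band[2]))
  rppg <- ppg_signal(roi_sig, band = band, seed = seed)
  cond <- condition_bank(y_signal_bank(traj), f_lo = band[1], f_hi = band[2])
  bank <- prune_by_snr(cond, band = band)
  rbcg <- bcg_signal(bank, band = band)
  rppg_z <- standardize(rppg)
  rbcg_z <- standardize(rbcg)
  if (stats::cor(rppg_z$samples, rbcg_z$samples) < 0) {
    rbcg_z <- signal1d(-rbcg_z$samples, rbcg_z$fs)
  }
  fused <- lapply(methods, function(m) {
    fuse(rppg_z, rbcg_z, m, band = band, seed = seed)
  })
  names(fused) <- methods
  n <- length(rppg$samples)
  if (n < round(window_s * rppg$fs)) {
    warning("run_pipeline: recording shorter than the window; ",
            "single whole-recording estimate per method")
    t1 <- n / rppg$fs
    series <- c(list(hr_series(t1, dominant_hr(rppg, band)$bpm, "RPPG"),
                     hr_series(t1, dominant_hr(rbcg, band)$bpm, "RBCG")),
                lapply(methods, function(m) {
                  hr_series(t1, dominant_hr(fused[[m]], band)$bpm, m)
                }))
    hr <- do.call(rbind, series)
    class(hr) <- c("hr_series", "data.frame")
  } else {
    hr <- windowed_pipeline_hr(roi_sig, bank, methods, window_s, stride_s,
                               band, seed)
  }
  structure(list(hr = hr,
                 signals = c(list(rppg = rppg, rbcg = rbcg), fused),
                 methods = methods, band = band, window_s = window_s,
                 stride_s = stride_s, resets = resets,
                 call = match.call()),
            class = "hr_fusion")
}

#' @export
print.hr_fusion <- function(x, ...) {
  cat("Camera-based heart-rate fusion\n")
  cat("  fusion method(s):", paste(x$methods, collapse = ", "), "\n")
  agg <- stats::aggregate(bpm ~ method, data = x$hr, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-5s mean HR %.1f bpm\n", agg$method[i], agg$bpm[i]))
  }
  if (length(x$resets)) {
    cat("  re-detections at frame(s):", paste(x$resets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hr_fusion <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object$hr, object$hr$method), function(d) {
    data.frame(method = d$method[1], n = nrow(d), mean_bpm = mean(d$bpm),
               sd_bpm = stats::sd(d$bpm), min_bpm = min(d$bpm),
               max_bpm = max(d$bpm))
  }))
  rownames(agg) <- NULL
  agg
}

#' Plot the estimated heart-rate series
#' @param x An `hr_fusion` object.
#' @param ... Passed to [graphics::matplot].
#' @export
plot.hr_fusion <- function(x, ...) {
  sp <- split(x$hr, x$hr$method)
  cols <- seq_along(sp)
  graphics::plot(NULL, xlim = range(x$hr$time), ylim = range(x$hr$bpm),
                 xlab = "Time (s)", ylab = "Heart rate (bpm)", ...)
  for (i in seq_along(sp)) {
    graphics::lines(sp[[i]]$time, sp[[i]]$bpm, col = cols[i])
  }
  graphics::legend("topright", legend = names(sp), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
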