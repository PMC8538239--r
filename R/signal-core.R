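# Shared numeric primitives: the Signal1D container, normalization,
# band-pass filtering, amplitude correction, power spectra, the spectral
# SNR statistic, and dominant-frequency heart-rate estimation.

#' Uniformly sampled scalar time series
#'
#' The universal currency between pipeline stages: a numeric sample vector
#' together with its sampling rate. All samples must be finite.
#'
#' @param samples Numeric vector, length >= 2, all finite.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `signal1d` with fields `samples` and `fs`.
#' @export
signal1d <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("signal1d: need at least 2 samples")
  if (!all(is.finite(samples))) stop("signal1d: samples must be finite")
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("signal1d: fs must be a positive scalar")
  }
  structure(list(samples = samples, fs = fs), class = "signal1d")
}

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal1d <- function(x) length(x$samples)

as_signal1d <- function(x, fs) {
  if (inherits(x, "signal1d")) x else signal1d(x, fs)
}

#' Subtract the mean of a signal
#'
#' Removes the DC component. For RGB traces the per-channel mean carries the
#' melanin (skin tone) component rather than the pulse, so extraction starts
#' by centering each channel; tracked-point trajectories are centered the
#' same way so both modalities live on a comparable zero-mean scale.
#'
#' @param s A [signal1d].
#' @return A zero-mean [signal1d] at the same sampling rate.
#' @export
mean_center <- function(s) {
  stopifnot(inherits(s, "signal1d"))
  signal1d(s$samples - mean(s$samples), s$fs)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given design order forward and
#' backward (zero phase), preserving the timing of the pulse peak. The
#' default 0.75--2.5 Hz band corresponds to 45--150 bpm.
#'
#' @param s A [signal1d].
#' @param f_lo,f_hi Band edges in Hz; must satisfy `f_lo < f_hi < fs/2`.
#' @param order Filter design order (default 2).
#' @return Filtered [signal1d], same length and sampling rate.
#' @export
bandpass <- function(s, f_lo = 0.75, f_hi = 2.5, order = 2L) {
  stopifnot(inherits(s, "signal1d"))
  fs <- s$fs
  if (!(f_lo < f_hi && f_hi < fs / 2)) {
    stop("bandpass: need f_lo < f_hi < fs/2 (band infeasible for this fs)")
  }
  if (length(s$samples) <= 3L * order) {
    stop("bandpass: signal too short for the requested filter order")
  }
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, s$samples)
  signal1d(y, fs)
}

#' Replace large-amplitude excursions by the mean
#'
#' Voluntary head movements distort motion signals with large transient
#' amplitudes; samples further than `k` standard deviations from the mean
#' are set to the mean. A single pass with thresholds computed from the
#' pre-replacement statistics; if the standard deviation is zero the signal
#' is returned unchanged.
#'
#' @param s A [signal1d].
#' @param k Threshold in multiples of the standard deviation (default 2).
#' @return Corrected [signal1d].
#' @export
clip_to_mean <- function(s, k = 2) {
  stopifnot(inherits(s, "signal1d"))
  x <- s$samples
  m <- mean(x)
  sdev <- stats::sd(x)
  if (!is.finite(sdev) || sdev == 0) return(s)
  x[abs(x - m) > k * sdev] <- m
  signal1d(x, s$fs)
}

#' Band-restricted power spectrum
#'
#' Mean-centers the signal, zero-pads so the FFT bin spacing is at most
#' 1/120 Hz (0.5 bpm), and returns the magnitude-squared spectrum restricted
#' to the analysis band (inclusive). A rectangular window is used.
#'
#' @param s A [signal1d] with at least 64 samples.
#' @param band Length-2 vector `(f_lo, f_hi)` in Hz, default `c(0.75, 2.5)`.
#' @return An object of class `power_spectrum` with fields `freqs`, `power`,
#'   and `band`.
#' @export
power_spectrum <- function(s, band = c(0.75, 2.5)) {
  stopifnot(inherits(s, "signal1d"))
  x <- s$samples
  if (length(x) < 64L) stop("power_spectrum: need at least 64 samples")
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(max(length(x), ceiling(120 * s$fs))))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  half <- seq_len(nfft %/% 2)
  freqs <- (half - 1) * s$fs / nfft
  power <- Mod(X[half])^2
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("power_spectrum: no FFT bins inside the band")
  structure(list(freqs = freqs[keep], power = power[keep],
                 band = as.numeric(band)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins in [%g, %g] Hz, peak at %.3f Hz\n",
              length(x$freqs), x$band[1], x$band[2],
              x$freqs[which.max(x$power)]))
  invisible(x)
}

#' Spectral signal-to-noise ratio
#'
#' The selection statistic used throughout the pipeline:
#' `SNR = max(PS) / (sum(PS) - max(PS))`, the power of the largest spectral
#' bin over the power of everything else in the band. Ties are broken by the
#' single maximal bin, counted once in the numerator.
#'
#' @param ps A [power_spectrum] with at least 2 bins.
#' @return A non-negative number; `Inf` when all power sits in one bin.
#' @export
snr <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  p <- ps$power
  if (length(p) < 2L) stop("snr: need at least 2 spectral bins")
  total <- sum(p)
  if (total == 0) stop("snr: all-zero spectrum")
  mx <- max(p)
  denom <- total - mx
  if (denom <= 0) return(Inf)
  mx / denom
}

#' Heart rate from the dominant in-band frequency
#'
#' Finds the in-band FFT bin with maximal power and converts it to beats per
#' minute: `HR = 60 * freq`. Ties are broken toward the lower frequency.
#'
#' @param s A [signal1d].
#' @param band Analysis band in Hz, default `c(0.75, 2.5)` (45--150 bpm).
#' @return An object of class `hr_estimate` with fields `bpm`,
#'   `dominant_freq` (Hz), and `snr`.
#' @export
dominant_hr <- function(s, band = c(0.75, 2.5)) {
  ps <- power_spectrum(s, band)
  i <- which.max(ps$power)  # first maximum = lowest-frequency tie
  structure(list(bpm = 60 * ps$freqs[i],
                 dominant_freq = ps$freqs[i],
                 snr = snr(ps)),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %.1f bpm (%.4f Hz), SNR = %.3g\n",
              x$bpm, x$dominant_freq, x$snr))
  invisible(x)
}

#' Standardize a signal to zero mean and unit variance
#'
#' Color and pixel units have incomparable magnitudes; both pulse signals
#' are standardized before fusion so ensemble averaging is not dominated by
#' one modality.
#'
#' @param s A [signal1d] with non-zero variance.
#' @return Standardized [signal1d].
#' @export
standardize <- function(s) {
  stopifnot(inherits(s, "signal1d"))
  sdev <- stats::sd(s$samples)
  if (!is.finite(sdev) || sdev == 0) stop("standardize: constant signal")
  signal1d((s$samples - mean(s$samples)) / sdev, s$fs)
}

# SNR of a raw sample vector at a given rate (internal shorthand).
snr_of <- function(x, fs, band = c(0.75, 2.5)) {
  if (stats::sd(x) == 0) return(-Inf)
  tryCatch(snr(power_spectrum(signal1d(x, fs), band)), error = function(e) -Inf)
}

# Select the column of `mat` with maximal spectral SNR; near-ties (within
# 1e-9) resolved toward the lower dominant frequency. Returns the index.
select_by_snr <- function(mat, fs, band = c(0.75, 2.5)) {
  snrs <- apply(mat, 2L, snr_of, fs = fs, band = band)
  best <- max(snrs)
  cand <- which(snrs >= best - 1e-9 | (is.infinite(best) & is.infinite(snrs)))
  if (length(cand) > 1L) {
    domf <- vapply(cand, function(j) {
      tryCatch(dominant_hr(signal1d(mat[, j], fs), band)$dominant_freq,
               error = function(e) Inf)
    }, numeric(1))
    cand <- cand[which.min(domf)]
  }
  cand[1L]
}
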