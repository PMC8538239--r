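# Fusing the color-based (RPPG) and motion-based (RBCG) pulse signals into
# one combined pulse signal by ensemble averaging, PCA, or ICA, with
# SNR-based component selection for the BSS variants.

FUSION_METHODS <- c("EA", "PCA", "ICA")

#' Validate a fusion method label
#' @param name One of `"EA"`, `"PCA"`, `"ICA"` (case-insensitive).
#' @return Canonical upper-case label.
#' @export
fusion_method <- function(name) {
  m <- toupper(as.character(name))
  if (length(m) != 1L || !m %in% FUSION_METHODS) {
    stop("fusion_method: unknown method '", name,
         "' (expected EA, PCA, or ICA)")
  }
  m
}

check_fusable <- function(rppg, rbcg) {
  stopifnot(inherits(rppg, "signal1d"), inherits(rbcg, "signal1d"))
  if (length(rppg$samples) != length(rbcg$samples) || rppg$fs != rbcg$fs) {
    stop("fuse: signals must share length and sampling rate")
  }
}

#' Ensemble-average fusion
#'
#' The element-wise mean of the two pulse signals,
#' `EA = (RPPG + RBCG) / 2`. Uncorrelated noise in the two modalities
#' attenuates while the shared cardiac component is preserved. Callers are
#' expected to pass standardized (zero-mean, unit-variance) inputs so
#' neither modality dominates.
#'
#' @param rppg,rbcg [signal1d]s of equal length and sampling rate.
#' @return The averaged [signal1d].
#' @export
fuse_ea <- function(rppg, rbcg) {
  check_fusable(rppg, rbcg)
  signal1d((rppg$samples + rbcg$samples) / 2, rppg$fs)
}

#' Blind-source-separation fusion (PCA or ICA)
#'
#' Decomposes the two signals into two components (capped at the rank of the
#' pair) and returns the component with the highest spectral SNR, normalized
#' to unit standard deviation. ICA non-convergence falls back to PCA with a
#' warning.
#'
#' @param rppg,rbcg [signal1d]s of equal length and sampling rate.
#' @param method `"PCA"` or `"ICA"`.
#' @param band Analysis band for SNR selection.
#' @param seed Seed for the deterministic ICA initialization.
#' @return A unit-variance [signal1d].
#' @export
fuse_bss <- function(rppg, rbcg, method, band = c(0.75, 2.5), seed = 42L) {
  method <- fusion_method(method)
  if (method == "EA") stop("fuse_bss: method must be PCA or ICA")
  check_fusable(rppg, rbcg)
  X <- cbind(rppg$samples, rbcg$samples)
  comps <- if (method == "ICA") {
    tryCatch({
      res <- fast_ica(X, n_comp = 2L, seed = seed)
      if (!res$converged) stop("ICA did not converge")
      res$S
    }, error = function(e) {
      warning("fuse_bss: ICA unavailable (", conditionMessage(e),
              "); falling back to PCA")
      pca_scores(X, 2L)
    })
  } else {
    pca_scores(X, 2L)
  }
  j <- select_by_snr(comps, rppg$fs, band)
  out <- comps[, j]
  signal1d(out / stats::sd(out), rppg$fs)
}

#' Fuse the two pulse signals
#'
#' Dispatches on the fusion method: `"EA"` to [fuse_ea], `"PCA"`/`"ICA"` to
#' [fuse_bss].
#'
#' @inheritParams fuse_bss
#' @param method `"EA"`, `"PCA"`, or `"ICA"`.
#' @return The fused [signal1d].
#' @export
fuse <- function(rppg, rbcg, method = "EA", band = c(0.75, 2.5), seed = 42L) {
  method <- fusion_method(method)
  if (method == "EA") fuse_ea(rppg, rbcg)
  else fuse_bss(rppg, rbcg, method, band = band, seed = seed)
}
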