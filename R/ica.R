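# Deterministic FastICA: eigen-whitening followed by the symmetric
# fixed-point iteration with the logcosh (tanh) contrast. The initial
# unmixing matrix is a seeded orthonormal matrix so repeated runs are
# bit-identical; the caller's RNG state is saved and restored.

# Evaluate `code` under a temporary RNG seed, restoring global state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a sub-seed from (seed, tag), kept within 32-bit integer range.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + tag) %% 2147483647)
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' Independent component analysis (deterministic FastICA)
#'
#' Whitens the columns of `X` by eigendecomposition of the sample covariance
#' (dropping near-zero eigenvalues, so rank-deficient inputs yield fewer
#' components) and runs the symmetric fixed-point iteration with the logcosh
#' contrast from a seeded orthonormal start.
#'
#' @param X Numeric matrix, samples in rows, mixed channels in columns.
#' @param n_comp Number of components requested (capped at the rank of `X`).
#' @param seed Integer seed for the initial unmixing matrix.
#' @param max_iter,tol Iteration controls.
#' @return List with `S` (samples x components source matrix, unit-variance
#'   columns), `n_comp` (components actually returned), and `converged`.
#' @export
fast_ica <- function(X, n_comp = ncol(X), seed = 42L,
                     max_iter = 200L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  cv <- stats::cov(Xc)
  e <- eigen(cv, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9 & e$values > 0
  r <- min(sum(keep), n_comp)
  if (r < 1L) stop("fast_ica: input has rank 0")
  K <- e$vectors[, seq_len(r), drop = FALSE] %*%
    diag(1 / sqrt(e$values[seq_len(r)]), r)
  Z <- Xc %*% K  # whitened: cov(Z) = I_r
  if (r == 1L) {
    s <- Z[, 1]
    return(list(S = matrix(s / stats::sd(s), ncol = 1), n_comp = 1L,
                converged = TRUE))
  }
  W <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(r * r), r, r))))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)          # n x r
    G <- tanh(WX)
    gp <- 1 - G^2
    W1 <- crossprod(G, Z) / n - diag(colMeans(gp), r) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- Z %*% t(W)
  S <- sweep(S, 2L, apply(S, 2L, stats::sd), "/")
  list(S = S, n_comp = r, converged = converged)
}

# PCA score series of the columns of X (samples x channels), capped at
# `n_comp` components. Used both as the BCG decomposition and as the
# fallback when ICA does not converge.
pca_scores <- function(X, n_comp) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) {
    warning("pca_scores: fewer samples than channels; reduced-rank PCA")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_comp, ncol(pr$x))
  pr$x[, seq_len(k), drop = FALSE]
}
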