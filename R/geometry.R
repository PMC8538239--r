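# Face-relative ROI geometry, the 80-point measurement grid, pyramidal
# Lucas-Kanade point tracking, and the similarity transform that carries
# the ROIs between frames.
#
# Image convention: frames are numeric arrays [height, width, 3] (or
# matrices for grayscale) on an 8-bit 0-255 scale. Coordinates are
# continuous and zero-based: pixel (row i, col j) covers x in [j-1, j),
# y in [i-1, i), with its center at (j - 0.5, i - 0.5). Rectangles are
# half-open [x0, x1) x [y0, y1).

#' Face bounding box
#' @param x,y Left/top edge in pixels.
#' @param w,h Width/height in pixels (> 0).
#' @param frame_index Zero-based frame index.
#' @return Object of class `face_box`.
#' @export
face_box <- function(x, y, w, h, frame_index = 0L) {
  if (w <= 0 || h <= 0) stop("face_box: w and h must be positive")
  if (frame_index < 0) stop("face_box: frame_index must be >= 0")
  structure(list(x = x, y = y, w = w, h = h,
                 frame_index = as.integer(frame_index)),
            class = "face_box")
}

#' Axis-aligned region of interest
#' @param name One of `"forehead"`, `"nose"`, `"left_cheek"`, `"right_cheek"`.
#' @param x0,y0,x1,y1 Corner coordinates in pixels; half-open rect.
#' @return Object of class `roi_rect`.
#' @export
roi_rect <- function(name, x0, y0, x1, y1) {
  name <- match.arg(name, c("forehead", "nose", "left_cheek", "right_cheek"))
  if (!(x1 > x0 && y1 > y0)) stop("roi_rect: degenerate rectangle")
  structure(list(name = name, x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi_rect")
}

# Round half away from zero (deterministic raster addressing).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Face-relative measurement regions
#'
#' Derives the four sub-regions of the face used for pulse extraction:
#' forehead (middle 50% of width, top 20% of height), nose (middle 50% of
#' width, vertically centered 25% of height), left cheek (20--35% of width,
#' 45--70% of height), and the mirrored right cheek (65--80% of width).
#' Fractional coordinates are rounded half away from zero to integer pixels.
#'
#' @param face A [face_box]; width and height must be at least 20 px.
#' @return Named list of four [roi_rect]s.
#' @export
compute_rois <- function(face) {
  stopifnot(inherits(face, "face_box"))
  if (face$w < 20 || face$h < 20) {
    stop("compute_rois: face box too small to be a usable detection")
  }
  frac_rect <- function(name, fx0, fy0, fx1, fy1) {
    roi_rect(name,
             round_half_away(face$x + fx0 * face$w),
             round_half_away(face$y + fy0 * face$h),
             round_half_away(face$x + fx1 * face$w),
             round_half_away(face$y + fy1 * face$h))
  }
  list(
    forehead    = frac_rect("forehead",    0.25, 0.000, 0.75, 0.200),
    nose        = frac_rect("nose",        0.25, 0.375, 0.75, 0.625),
    left_cheek  = frac_rect("left_cheek",  0.20, 0.450, 0.35, 0.700),
    right_cheek = frac_rect("right_cheek", 0.65, 0.450, 0.80, 0.700)
  )
}

#' The 80-point measurement grid
#'
#' Divides the forehead into 32 cells (8 columns x 4 rows) and the nose into
#' 48 cells (8 columns x 6 rows) and places one point at the center of each
#' cell, row-major. The y-trajectories of these points carry the
#' ballistocardiographic signal.
#'
#' @param forehead,nose [roi_rect]s for the two regions.
#' @return Object of class `point_grid`: `points` (80 x 2 matrix of x, y)
#'   and `region` (character vector of per-point labels).
#' @export
make_point_grid <- function(forehead, nose) {
  stopifnot(inherits(forehead, "roi_rect"), inherits(nose, "roi_rect"))
  cell_centers <- function(r, ncol_, nrow_) {
    cw <- (r$x1 - r$x0) / ncol_
    ch <- (r$y1 - r$y0) / nrow_
    if (cw < 2 || ch < 2) {
      stop("make_point_grid: region too small to host its grid (cell < 2 px)")
    }
    xs <- r$x0 + (seq_len(ncol_) - 0.5) * cw
    ys <- r$y0 + (seq_len(nrow_) - 0.5) * ch
    cbind(x = rep(xs, times = nrow_), y = rep(ys, each = ncol_))
  }
  pf <- cell_centers(forehead, 8L, 4L)
  pn <- cell_centers(nose, 8L, 6L)
  structure(list(points = rbind(pf, pn),
                 region = c(rep("forehead", 32L), rep("nose", 48L))),
            class = "point_grid")
}

#' Planar similarity transform (translation, rotation, isotropic scale)
#' @param scale Positive scale factor.
#' @param rotation Rotation in radians.
#' @param tx,ty Translation in pixels.
#' @return Object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, tx = 0, ty = 0) {
  if (scale <= 0) stop("similarity_transform: scale must be positive")
  structure(list(scale = scale, rotation = rotation, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' Least-squares similarity transform between point sets
#'
#' Fits the 4-degree-of-freedom transform (scale, rotation, translation)
#' mapping `src` onto `dst` by minimizing the summed squared residual. Exact
#' (residual ~ machine precision) for noiseless similarity-transformed input.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 2.
#' @return A [similarity_transform].
#' @export
estimate_similarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  if (nrow(src) < 2L) stop("estimate_similarity: need >= 2 correspondences")
  ms <- colMeans(src); md <- colMeans(dst)
  sc <- sweep(src, 2L, ms); dc <- sweep(dst, 2L, md)
  denom <- sum(sc^2)
  if (denom < .Machine$double.eps) {
    stop("estimate_similarity: coincident source points (rank deficiency)")
  }
  a <- sum(sc[, 1] * dc[, 1] + sc[, 2] * dc[, 2]) / denom
  b <- sum(sc[, 1] * dc[, 2] - sc[, 2] * dc[, 1]) / denom
  sca <- sqrt(a^2 + b^2)
  rot <- atan2(b, a)
  tx <- md[1] - (a * ms[1] - b * ms[2])
  ty <- md[2] - (b * ms[1] + a * ms[2])
  similarity_transform(sca, rot, tx, ty)
}

#' Apply a similarity transform to points
#' @param t A [similarity_transform].
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "similarity_transform"))
  pts <- as.matrix(pts)
  a <- t$scale * cos(t$rotation)
  b <- t$scale * sin(t$rotation)
  cbind(a * pts[, 1] - b * pts[, 2] + t$tx,
        b * pts[, 1] + a * pts[, 2] + t$ty)
}

#' Carry a rectangle through a similarity transform
#'
#' Maps the four corners and returns the axis-aligned bounding box of the
#' result, preserving the region name.
#'
#' @param t A [similarity_transform].
#' @param rect A [roi_rect].
#' @return A [roi_rect].
#' @export
apply_transform <- function(t, rect) {
  stopifnot(inherits(rect, "roi_rect"))
  corners <- rbind(c(rect$x0, rect$y0), c(rect$x1, rect$y0),
                   c(rect$x0, rect$y1), c(rect$x1, rect$y1))
  m <- transform_points(t, corners)
  roi_rect(rect$name, min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
}

# ---- Pyramidal Lucas-Kanade tracking --------------------------------------

to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Bilinear interpolation at continuous (x, y); coordinates clamped to the
# image interior. x, y are vectors.
interp2 <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- x + 0.5  # fractional column index
  cy <- y + 0.5
  cx[cx < 1] <- 1; cx[cx > nc] <- nc
  cy[cy < 1] <- 1; cy[cy > nr] <- nr
  x0 <- floor(cx); x0[x0 > nc - 1L] <- nc - 1L
  y0 <- floor(cy); y0[y0 > nr - 1L] <- nr - 1L
  fx <- cx - x0; fy <- cy - y0
  i00 <- (x0 - 1L) * nr + y0
  v00 <- img[i00]; v10 <- img[i00 + nr]
  v01 <- img[i00 + 1L]; v11 <- img[i00 + nr + 1L]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Central-difference gradient image along dimension `dim` (1 = rows/y,
# 2 = columns/x), replicated edges.
grad_img <- function(img, dim) {
  nr <- nrow(img); nc <- ncol(img)
  g <- img
  if (dim == 2L) {
    g[, 2:(nc - 1L)] <- (img[, 3:nc] - img[, 1:(nc - 2L)]) / 2
    g[, 1L] <- img[, 2L] - img[, 1L]
    g[, nc] <- img[, nc] - img[, nc - 1L]
  } else {
    g[2:(nr - 1L), ] <- (img[3:nr, ] - img[1:(nr - 2L), ]) / 2
    g[1L, ] <- img[2L, ] - img[1L, ]
    g[nr, ] <- img[nr, ] - img[nr - 1L, ]
  }
  g
}

# Downsample an image by 2 (2x2 block average).
pyr_down <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
     img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr[[l]])) < 16L) { pyr <- pyr[seq_len(l)]; break }
    pyr[[l + 1L]] <- pyr_down(pyr[[l]])
  }
  pyr
}

# Iterative LK displacement for all points at one pyramid level,
# vectorised across points. pts: n x 2 at this level's scale; d: n x 2
# initial displacement guess. Returns list(d, ok).
lk_level <- function(prev, nxt, pts, d, hw, max_iter = 10L, eps = 0.01) {
  n <- nrow(pts)
  d0 <- d
  off <- as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw))
  m <- nrow(off)
  gx <- rep(pts[, 1], each = m) + rep(off[, 1], times = n)
  gy <- rep(pts[, 2], each = m) + rep(off[, 2], times = n)
  Tpl <- interp2(prev, gx, gy)
  Ix <- interp2(grad_img(prev, 2L), gx, gy)
  Iy <- interp2(grad_img(prev, 1L), gx, gy)
  grp <- rep(seq_len(n), each = m)
  sxx <- colSums(matrix(Ix * Ix, m)); syy <- colSums(matrix(Iy * Iy, m))
  sxy <- colSums(matrix(Ix * Iy, m))
  det <- sxx * syy - sxy^2
  ok <- det > 1e-6 * (2 * hw + 1)^2
  active <- ok
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ai <- which(active)
    sub <- active[grp]
    qx <- gx[sub] + rep(d[ai, 1], each = m)
    qy <- gy[sub] + rep(d[ai, 2], each = m)
    E <- interp2(nxt, qx, qy) - Tpl[sub]
    bx <- colSums(matrix(Ix[sub] * E, m))
    by <- colSums(matrix(Iy[sub] * E, m))
    ux <- ( syy[ai] * bx - sxy[ai] * by) / det[ai]
    uy <- (-sxy[ai] * bx + sxx[ai] * by) / det[ai]
    d[ai, 1] <- d[ai, 1] - ux
    d[ai, 2] <- d[ai, 2] - uy
    active[ai] <- (abs(ux) + abs(uy)) > eps
  }
  # divergence guard: an update larger than the search window means the
  # solver left the basin of the true match (flat or repetitive texture)
  lost <- sqrt(rowSums((d - d0)^2)) > (2 * hw + 1)
  d[lost, ] <- d0[lost, ]
  ok <- ok & !lost
  list(d = d, ok = ok)
}

# Displacement threshold triggering grid re-detection.
redetect_needed <- function(displacements, threshold = 10) {
  any(sqrt(rowSums(displacements^2)) > threshold)
}

#' Track grid points between two frames
#'
#' Estimates per-point displacement with a 3-level pyramidal Lucas-Kanade
#' tracker. The tracking window is supplied by the caller (by convention the
#' detected face size divided by 10). If any point moves more than 10 px the
#' `redetect` flag is raised and the caller should re-derive the ROIs and
#' grid on the current frame. Points whose local gradient structure is
#' degenerate are carried over unchanged and reported in `failed`.
#'
#' @param prev_frame,next_frame Grayscale matrices or RGB arrays of equal
#'   dimensions (0--255 scale).
#' @param points A [point_grid] of positions in `prev_frame`.
#' @param window Tracking window size in pixels (>= 3).
#' @param levels Pyramid levels (default 3).
#' @return List: `points` (tracked [point_grid]), `displacement` (n x 2),
#'   `redetect` (logical), `failed` (logical vector).
#' @export
track_points <- function(prev_frame, next_frame, points, window,
                         levels = 3L) {
  g_prev <- to_gray(prev_frame); g_next <- to_gray(next_frame)
  if (!all(dim(g_prev) == dim(g_next))) {
    stop("track_points: frames must have the same dimensions")
  }
  track_pyramids(build_pyramid(g_prev, levels), build_pyramid(g_next, levels),
                 points, window)
}

# Core pyramidal tracker on prebuilt pyramids (lets callers that walk a
# whole clip reuse each frame's pyramid instead of rebuilding it twice).
track_pyramids <- function(p_prev, p_next, points, window) {
  stopifnot(inherits(points, "point_grid"))
  if (window < 3) stop("track_points: window must be >= 3 px")
  hw <- max(1L, floor(window / 2))
  L <- min(length(p_prev), length(p_next))
  n <- nrow(points$points)
  d <- matrix(0, n, 2)
  # fast path: inter-frame motion is almost always well inside the window,
  # so a single fine-level solve usually suffices; fall back to the full
  # coarse-to-fine pyramid only when some point diverges (large motion)
  res <- lk_level(p_prev[[1L]], p_next[[1L]], points$points, d, hw = hw)
  ok_all <- res$ok
  d <- res$d
  if (any(!res$ok) && L > 1L) {
    d <- matrix(0, n, 2)
    for (l in L:1) {
      sc <- 2^(l - 1L)
      res <- lk_level(p_prev[[l]], p_next[[l]], points$points / sc, d,
                      hw = hw)
      d <- res$d
      if (l == 1L) ok_all <- res$ok
      if (l > 1L) d <- d * 2
    }
  }
  d[!ok_all, ] <- 0
  if (any(!ok_all)) {
    warning(sprintf("track_points: %d point(s) untrackable; carried over",
                    sum(!ok_all)))
  }
  new_pts <- points
  new_pts$points <- points$points + d
  list(points = new_pts, displacement = d,
       redetect = redetect_needed(d), failed = !ok_all)
}
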