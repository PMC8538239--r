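test_that("face-relative regions land on the documented fractions", {
  rois <- compute_rois(face_box(0, 0, 100, 100))
  f <- rois$forehead
  expect_equal(c(f$x0, f$y0, f$x1, f$y1), c(25, 0, 75, 20))
  n <- rois$nose
  expect_equal(c(n$x0, n$y0, n$x1, n$y1), c(25, 38, 75, 63))
  l <- rois$left_cheek
  expect_equal(c(l$x0, l$y0, l$x1, l$y1), c(20, 45, 35, 70))
  r <- rois$right_cheek
  expect_equal(c(r$x0, r$y0, r$x1, r$y1), c(65, 45, 80, 70))
  # regions translate with the face box
  f2 <- compute_rois(face_box(10, 20, 100, 100))$forehead
  expect_equal(c(f2$x0, f2$y0), c(35, 20))

  expect_error(compute_rois(face_box(0, 0, 10, 10)), "too small")
  expect_error(face_box(0, 0, -5, 10), "positive")
  expect_error(roi_rect("nose", 5, 5, 5, 10), "degenerate")
})

test_that("the measurement grid has 80 cell-centered points", {
  g <- make_point_grid(roi_rect("forehead", 0, 0, 80, 40),
                       roi_rect("nose", 0, 100, 80, 160))
  expect_s3_class(g, "point_grid")
  expect_equal(dim(g$points), c(80L, 2L))
  expect_identical(table(g$region)[["forehead"]], 32L)
  expect_identical(table(g$region)[["nose"]], 48L)
  # forehead: 8 x 4 cells of 10 x 10 px, first center at (5, 5), row-major
  expect_equal(unname(g$points[1, ]), c(5, 5))
  expect_equal(unname(g$points[2, ]), c(15, 5))
  expect_equal(unname(g$points[9, ]), c(5, 15))
  # nose: 8 x 6 cells, first center at (5, 105)
  expect_equal(unname(g$points[33, ]), c(5, 105))
  expect_error(
    make_point_grid(roi_rect("forehead", 0, 0, 8, 4),
                    roi_rect("nose", 0, 10, 80, 70)),
    "cell < 2 px")
})

test_that("estimate_similarity recovers a known transform exactly", {
  set.seed(2)
  src <- matrix(runif(40, 0, 100), ncol = 2)
  t_true <- similarity_transform(scale = 1.07, rotation = 0.2,
                                 tx = 4.5, ty = -2.25)
  dst <- transform_points(t_true, src)
  t_hat <- estimate_similarity(src, dst)
  expect_equal(t_hat$scale, 1.07, tolerance = 1e-9)
  expect_equal(t_hat$rotation, 0.2, tolerance = 1e-9)
  expect_equal(t_hat$tx, 4.5, tolerance = 1e-9)
  expect_equal(t_hat$ty, -2.25, tolerance = 1e-9)
  expect_lt(max(abs(transform_points(t_hat, src) - dst)), 1e-6)

  expect_error(estimate_similarity(src[1, , drop = FALSE],
                                   dst[1, , drop = FALSE]), ">= 2")
  same <- matrix(5, 4, 2)
  expect_error(estimate_similarity(same, same + 1), "coincident")
  expect_error(similarity_transform(scale = 0), "positive")
})

test_that("apply_transform carries a rectangle by its corner bounding box", {
  t <- similarity_transform(tx = 10, ty = -5)
  r <- apply_transform(t, roi_rect("nose", 0, 0, 20, 10))
  expect_equal(c(r$x0, r$y0, r$x1, r$y1), c(10, -5, 30, 5))
  # pure 90-degree rotation swaps the extents
  t90 <- similarity_transform(rotation = pi / 2)
  r90 <- apply_transform(t90, roi_rect("nose", 0, 0, 20, 10))
  expect_equal(r90$x1 - r90$x0, 10, tolerance = 1e-12)
  expect_equal(r90$y1 - r90$y0, 20, tolerance = 1e-12)
})

test_that("the tracker recovers a subpixel-accurate global translation", {
  # smooth, textured intensity field: gradients everywhere, no repetition
  big <- outer(1:120, 1:120, function(i, j) {
    128 + 45 * sin(0.31 * i + 0.17 * j) + 35 * cos(0.11 * i - 0.23 * j) +
      20 * sin(0.05 * i * 1.3 + 0.07 * j)
  })
  prev <- big[1:100, 1:100]
  nxt <- big[3:102, 4:103]  # content moves by dx = -3, dy = -2
  grid <- make_point_grid(roi_rect("forehead", 30, 25, 70, 45),
                          roi_rect("nose", 30, 50, 70, 80))
  res <- track_points(prev, nxt, grid, window = 10)
  expect_false(any(res$failed))
  expect_false(res$redetect)
  expect_lt(max(abs(res$displacement[, 1] - (-3))), 0.1)
  expect_lt(max(abs(res$displacement[, 2] - (-2))), 0.1)
  expect_equal(res$points$points, grid$points + rep(c(-3, -2), each = 80),
               tolerance = 0.1)

  # identical frames: zero displacement
  res0 <- track_points(prev, prev, grid, window = 10)
  expect_lt(max(abs(res0$displacement)), 1e-6)
})

test_that("re-detection triggers only beyond the 10 px displacement rule", {
  small <- matrix(c(3, 4, 0, 1), 2, 2)   # norms 3, ~4.1
  expect_false(redetect_needed(small))
  big <- matrix(c(3, 11, 0, 1), 2, 2)    # second point moves ~11 px
  expect_true(redetect_needed(big))
  expect_true(redetect_needed(small, threshold = 2))
})
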