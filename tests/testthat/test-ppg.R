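test_that("the pulse blood-volume direction is unit norm and green-dominant", {
  p <- default_pbv()
  expect_equal(sum(p^2), 1, tolerance = 1e-12)
  expect_true(p[2] >= p[1] && p[2] >= p[3])
  expect_warning(default_pbv(c(1, 0.2, 0.1)), "green")
})

test_that("rgb_trace validates channel lengths, range, and rate", {
  tr <- rgb_trace("nose", c(1, 2), c(3, 4), c(5, 6), 30)
  expect_s3_class(tr, "rgb_trace")
  expect_error(rgb_trace("nose", 1:3, 1:2, 1:3, 30), "lengths differ")
  expect_error(rgb_trace("nose", c(1, 300), c(1, 2), c(1, 2), 30), "255")
  expect_error(rgb_trace("nose", 1:2, 1:2, 1:2, 0), "fps")
  expect_error(rgb_trace("forehead", 1:2, 1:2, 1:2, 30))
})

test_that("pbv projection nulls a distortion and keeps the pulse", {
  fs <- 30
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 1.2 * t)
  distort <- 4 * sin(2 * pi * 0.3 * t) + 2 * cos(2 * pi * 2.0 * t)
  pbv <- default_pbv()
  dvec <- c(1, 1, 1) / sqrt(3)  # common illumination direction
  set.seed(41)
  # small sensor noise keeps the channel covariance full rank
  ch <- 120 + outer(pulse, pbv) + outer(distort, dvec) +
    matrix(stats::rnorm(3 * length(t), sd = 0.01), ncol = 3)
  out <- pbv_project(rgb_trace("nose", ch[, 1], ch[, 2], ch[, 3], fs))
  expect_s3_class(out, "signal1d")
  expect_gt(abs(stats::cor(out$samples, pulse)), 0.99)
  # the in-band 2 Hz distortion component is suppressed, not just filtered
  expect_lt(abs(stats::cor(out$samples, cos(2 * pi * 2.0 * t))), 0.1)

  short <- rgb_trace("nose", 1:10, 1:10, 1:10, fs)
  expect_error(pbv_project(short), "64 frames")
})

test_that("a rank-deficient channel covariance falls back with a warning", {
  fs <- 30
  x <- 100 + sin(seq_len(200))
  tr <- rgb_trace("nose", x, x, x, fs)  # identical channels: singular cov
  expect_warning(out <- pbv_project(tr), "singular")
  expect_length(out, 200L)
})

test_that("region traces are the spatial channel means of each frame", {
  frame <- array(0, c(40, 40, 3))
  frame[, , 1] <- 10; frame[, , 2] <- 20; frame[, , 3] <- 30
  rois <- compute_rois(face_box(0, 0, 40, 40))
  traces <- extract_rgb_traces(list(frame, frame, frame), rois, 30)
  expect_named(traces, c("nose", "left_cheek", "right_cheek"))
  for (tr in traces) {
    expect_equal(tr$r, rep(10, 3))
    expect_equal(tr$g, rep(20, 3))
    expect_equal(tr$b, rep(30, 3))
  }
  # a gradient frame distinguishes the regions
  frame[, , 1] <- matrix(rep(seq(0, 39), each = 40), 40)  # increases with x
  tr2 <- extract_rgb_traces(list(frame), rois, 30)
  expect_lt(tr2$left_cheek$r[1], tr2$right_cheek$r[1])

  off <- list(nose = roi_rect("nose", 30, 30, 50, 50),
              left_cheek = rois$left_cheek, right_cheek = rois$right_cheek)
  expect_warning(extract_rgb_traces(list(frame), off, 30), "clipped")
})

test_that("ppg_signal returns the unit-variance cardiac component", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 1.3 * t)
  set.seed(17)
  mk <- function(a, b) {
    s <- a * pulse + b * stats::rnorm(length(t))
    bandpass(signal1d(s, fs))
  }
  sigs <- list(mk(1, 0.3), mk(0.8, 0.4), mk(1.2, 0.5))
  out <- suppressWarnings(ppg_signal(sigs, seed = 1L))
  expect_equal(stats::sd(out$samples), 1, tolerance = 1e-9)
  expect_lt(abs(dominant_hr(out)$bpm - 78), 1)

  bad <- list(sigs[[1]], sigs[[2]], signal1d(rnorm(10), fs))
  expect_error(ppg_signal(bad), "share length")
})
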