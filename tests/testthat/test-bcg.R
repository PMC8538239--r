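test_that("trajectory and signal banks validate their inputs", {
  xs <- matrix(1, 4, 100); ys <- matrix(2, 4, 100)
  tb <- trajectory_bank(xs, ys, 30)
  expect_s3_class(tb, "trajectory_bank")
  expect_identical(tb$n_points, 4L)
  expect_identical(tb$n_frames, 100L)
  expect_output(print(tb), "4 points x 100 frames")
  expect_error(trajectory_bank(xs, ys[, 1:50], 30), "shape mismatch")
  expect_error(trajectory_bank(xs, ys, 0), "fps")
  ys[1, 1] <- NA
  expect_error(trajectory_bank(xs, ys, 30), "finite")

  sb <- signal_bank(matrix(rnorm(200), 2), 30)
  expect_identical(sb$channel_ids, 1:2)
  expect_output(print(sb), "2 channels x 100 samples")
  expect_error(signal_bank(matrix(c(1, Inf), 1), 30), "finite")
})

test_that("y_signal_bank centers each vertical trajectory", {
  set.seed(3)
  ys <- matrix(rnorm(5 * 128, mean = 40), 5)
  tb <- trajectory_bank(matrix(0, 5, 128), ys, 30)
  bank <- y_signal_bank(tb)
  expect_equal(unname(rowMeans(bank$channels)), rep(0, 5), tolerance = 1e-12)
  expect_equal(bank$channels[3, ], ys[3, ] - mean(ys[3, ]))
  short <- trajectory_bank(matrix(0, 5, 30), matrix(0, 5, 30), 30)
  expect_error(y_signal_bank(short), "64 frames")
})

test_that("condition_bank band-passes channels and zeroes flat ones", {
  fs <- 30
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  chans <- rbind(sin(2 * pi * 1.2 * t),   # in band: survives
                 sin(2 * pi * 5.0 * t),   # out of band: suppressed
                 rep(7, length(t)))       # constant: zeroed
  out <- condition_bank(signal_bank(chans, fs))
  core <- 150:750
  expect_gt(stats::sd(out$channels[1, core]), 0.5)
  expect_lt(stats::sd(out$channels[2, core]), 0.05)
  expect_equal(out$channels[3, ], rep(0, length(t)))
})

test_that("SNR pruning keeps the periodic channel, never empties the bank", {
  set.seed(9)
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  chans <- rbind(sin(2 * pi * 1.1 * t),
                 stats::rnorm(length(t)),
                 stats::rnorm(length(t)),
                 stats::rnorm(length(t)))
  pruned <- prune_by_snr(signal_bank(chans, fs))
  expect_true(1L %in% pruned$channel_ids)
  expect_lt(nrow(pruned$channels), 4L)
  # all-identical SNRs: everything is kept, nothing crashes
  same <- signal_bank(rbind(sin(2 * pi * t), sin(2 * pi * t)), fs)
  expect_identical(nrow(prune_by_snr(same)$channels), 2L)
  one <- signal_bank(matrix(rnorm(100), 1), fs)
  expect_error(prune_by_snr(one), "2 channels")
})

test_that("bcg_signal returns the unit-variance cardiac component", {
  set.seed(13)
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 1.4 * t)
  chans <- do.call(rbind, lapply(1:6, function(i) {
    pulse * (0.5 + 0.1 * i) + 0.3 * stats::rnorm(length(t))
  }))
  out <- bcg_signal(signal_bank(chans, fs))
  expect_equal(stats::sd(out$samples), 1, tolerance = 1e-9)
  expect_lt(abs(dominant_hr(out)$bpm - 84), 1)
  # single channel: standardized passthrough
  one <- bcg_signal(signal_bank(matrix(pulse, 1), fs))
  expect_gt(abs(stats::cor(one$samples, pulse)), 0.999)
  expect_equal(stats::sd(one$samples), 1, tolerance = 1e-9)
})
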