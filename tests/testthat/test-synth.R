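test_that("sim_config validates durations, rates, and amplitudes", {
  cfg <- sim_config(duration = 30)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(duration = 5), ">= 20")
  expect_error(sim_config(fps = 5), ">= 10")
  expect_error(sim_config(illum_amp = -1), ">= 0")
  expect_error(sim_config(expression_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(hr_bpm = 200), "45-150")
  expect_error(sim_config(hr_bpm = matrix(1:6, 2)), "scalar or")
})

test_that("ground truth follows the configured trajectory", {
  cfg <- sim_config(duration = 30, fps = 30, hr_bpm = 72)
  gt <- ground_truth(cfg)
  expect_identical(nrow(gt), 900L)
  expect_true(all(gt$bpm == 72))
  ramp <- sim_config(duration = 120, hr_bpm = cbind(c(0, 120), c(60, 90)))
  gr <- ground_truth(ramp)
  expect_equal(gr$bpm[1], 60)
  expect_equal(gr$bpm[nrow(gr)], 90, tolerance = 0.05)
  expect_true(all(diff(gr$bpm) >= 0))
})

test_that("the pulse waveform's dominant frequency matches the heart rate", {
  cfg <- sim_config(duration = 60, hr_bpm = 72)
  w <- pulse_waveform(cfg)
  expect_lt(abs(dominant_hr(w)$bpm - 72), 0.5)
  # amplitude bounded by fundamental + 0.3 harmonic
  expect_lte(max(abs(w$samples)), 1.3)
})

test_that("simulation is bit-for-bit reproducible under the same seed", {
  cfg <- sim_config(duration = 25, seed = 42)
  expect_identical(simulate_rgb(cfg), simulate_rgb(cfg))
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
  cfg2 <- sim_config(duration = 25, seed = 43)
  expect_false(identical(simulate_rgb(cfg)$traces$nose$g,
                         simulate_rgb(cfg2)$traces$nose$g))
})

test_that("simulated channel means sit at the configured skin baseline", {
  cfg <- sim_config(duration = 60, seed = 2)
  traces <- simulate_rgb(cfg)$traces
  for (tr in traces) {
    expect_lt(abs(mean(tr$r) - 150), 0.5)
    expect_lt(abs(mean(tr$g) - 110), 0.5)
    expect_lt(abs(mean(tr$b) - 95), 0.5)
    expect_true(all(tr$r >= 0 & tr$r <= 255))
  }
})

test_that("simulated trajectories carry 80 points for every frame", {
  cfg <- sim_config(duration = 20, seed = 5)
  trj <- simulate_trajectories(cfg)$traj
  expect_s3_class(trj, "trajectory_bank")
  expect_identical(trj$n_points, 80L)
  expect_identical(trj$n_frames, 600L)
  expect_identical(table(trj$region)[["forehead"]], 32L)
  expect_identical(table(trj$region)[["nose"]], 48L)
})

test_that("a transient movement event displaces the trajectories", {
  quiet <- sim_config(duration = 30, seed = 6, motion_rate = 0,
                      jitter_px = 0, resp_amp = 0, sway_px = 0, bcg_amp = 0)
  moving <- sim_config(duration = 30, seed = 6, motion_rate = 6,
                       jitter_px = 0, resp_amp = 0, sway_px = 0, bcg_amp = 0)
  rq <- apply(simulate_trajectories(quiet)$traj$ys, 1, function(y) diff(range(y)))
  rm_ <- apply(simulate_trajectories(moving)$traj$ys, 1, function(y) diff(range(y)))
  expect_gt(mean(rm_), mean(rq) + 1)
})

test_that("hrv_trajectory stays within its deviation bounds", {
  tr <- hrv_trajectory(180, base = 72, sd = 2, max_dev = 6, seed = 4)
  expect_true(all(abs(tr[, "bpm"] - 72) <= 6 + 1e-12))
  expect_true(all(tr[, "bpm"] >= 45 & tr[, "bpm"] <= 150))
  expect_identical(tr, hrv_trajectory(180, base = 72, sd = 2, max_dev = 6,
                                      seed = 4))
  expect_false(identical(tr, hrv_trajectory(180, seed = 5)))
})

test_that("scenario presets encode the three study conditions", {
  nm <- scenario("normal", duration = 30, seed = 1)
  ex <- scenario("expressions", duration = 30, seed = 1)
  hc <- scenario("hci", duration = 30, seed = 1)
  expect_identical(nm$motion_rate, 0)
  expect_identical(nm$expression_fraction, 0)
  expect_gt(ex$motion_rate, 0)
  expect_gt(ex$expression_fraction, 0)
  expect_gt(hc$illum_amp, nm$illum_amp)
  expect_gt(hc$motion_rate, ex$motion_rate)
  # heart rate defaults to a seeded physiological trajectory
  expect_true(is.matrix(nm$hr_bpm))
  expect_identical(scenario("normal", duration = 30, seed = 1)$hr_bpm,
                   nm$hr_bpm)
  # overrides pass through
  expect_identical(scenario("normal", duration = 30, hr_bpm = 80)$hr_bpm, 80)
  expect_error(scenario("outdoors"), "arg")
})

test_that("rendered clips expose frames, boxes, and the underlying truth", {
  cfg <- sim_config(duration = 20, seed = 8)
  clip <- render_clip(cfg, width = 320L, height = 240L)
  expect_s3_class(clip, "synthetic_clip")
  expect_identical(clip$n_frames, 600L)
  fr <- clip$frame(1L)
  expect_identical(dim(fr), c(240L, 320L, 3L))
  expect_true(all(fr >= 0 & fr <= 255))
  expect_identical(clip$frame(1L), clip$frame(1L))  # deterministic rendering
  expect_identical(nrow(clip$boxes), 600L)
  expect_true(all(c("frame_index", "x", "y", "w", "h") %in%
                    names(clip$boxes)))
  expect_s3_class(clip$traj, "trajectory_bank")
  expect_named(clip$traces, c("nose", "left_cheek", "right_cheek"))
  expect_output(print(clip), "synthetic_clip")
})
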