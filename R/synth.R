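# Synthetic-data generator: a quasi-periodic cardiac waveform at a known
# (possibly time-varying) rate drives both modalities -- RGB traces modulated
# along the pulse blood-volume direction with illumination noise, and
# 80-point trajectories carrying a small vertical ballistocardiographic
# oscillation with transient motion events, expression artifacts, and
# tracking jitter. Scenario presets mirror the three study conditions
# (normal, facial expressions, human-computer interaction). Everything is
# deterministic given the seed.

# Fixed characteristics of the noise model (see the methods vignette).
# Illumination is a mixture of three components: fast flicker band-limited
# to illum_band, a wandering narrowband interference (reflected screen /
# ambient luminance whose frequency drifts through the upper analysis band
# and above), and a 1/f broadband floor. The flicker hits the channels with
# unequal gains (warm light); the floor is independent per channel.
# Expression artifacts are low-frequency muscle movements of a few pixels
# on a subset of points.
ILLUM_CHANNEL_GAIN <- c(1, 0.85, 0.7)
ILLUM_W_FLICKER <- 0.5
ILLUM_W_WANDER <- 0.2
ILLUM_W_FLOOR <- 0.15
ILLUM_WANDER_BAND <- c(1.5, 4)  # Hz
SWAY_BAND <- c(0.3, 3)          # involuntary postural head sway, Hz
COLOR_TONE_BAND <- c(0.7, 2.6)  # nonstationary in-band color residue, Hz
EXPRESSION_SD <- 3      # px
EXPRESSION_BAND <- c(0.3, 1.5)  # Hz
RESP_BAND <- c(0.2, 0.35)      # Hz, respiratory sway
AMP_MOD_BAND <- c(0.02, 0.15)  # Hz, pulse-amplitude modulation

# Slowly varying positive pulse-amplitude envelope (vasomotion on the color
# side, stroke volume on the motion side).
pulse_envelope <- function(n, fs, depth) {
  if (depth == 0) return(rep(1, n))
  pmax(1 + depth * noise_bandlimited(n, fs, AMP_MOD_BAND[1], AMP_MOD_BAND[2]),
       0.2)
}

#' Simulation configuration
#'
#' Encodes one synthetic recording. Defaults mirror the study conditions:
#' 3-minute recordings at 30 fps, resting heart rate 72 bpm, sub-unit color
#' modulation (0.2 8-bit units on the green channel scale), 0.35 px vertical
#' head oscillation (the ~0.5 mm ballistocardiographic displacement at
#' webcam scale, where a face spans roughly 100 px), 0.4 px tracker jitter,
#' respiratory sway with in-band harmonics, sub-pixel postural sway, and
#' in-band sensor/color residue -- the always-on noise floor that makes the
#' single modalities imperfect even under the `normal` preset.
#'
#' @param duration Recording length in seconds (>= 20).
#' @param fps Frame rate in Hz (>= 10).
#' @param hr_bpm Heart rate: a scalar, or a 2-column matrix / data frame of
#'   (time, bpm) breakpoints for a piecewise-linear trajectory; 45--150 bpm.
#' @param pulse_amp_rgb Pulse color amplitude in 8-bit units.
#' @param pbv Unit pulse blood-volume direction (see [default_pbv]).
#' @param bcg_amp Vertical ballistocardiographic amplitude in pixels.
#' @param illum_amp Illumination noise amplitude (8-bit units, sd).
#' @param illum_band Frequency band of the illumination flicker, Hz.
#' @param motion_rate Transient head-movement events per minute.
#' @param motion_amp Peak amplitude of a movement event in pixels.
#' @param expression_fraction Fraction of points carrying expression
#'   artifacts (0--1).
#' @param jitter_px Tracking jitter standard deviation in pixels.
#' @param sensor_noise Camera sensor/compression noise on the ROI channel
#'   means, standard deviation in 8-bit units.
#' @param resp_amp Respiratory head-sway amplitude in pixels
#'   (band-limited to 0.2--0.35 Hz, shared across points).
#' @param sway_px Involuntary postural head-sway amplitude in pixels:
#'   broadband (0.3--3 Hz) whole-head micro-motion that overlaps the pulse
#'   band, present even in motionless subjects.
#' @param color_noise Nonstationary narrowband color interference amplitude
#'   in 8-bit units: slowly wandering in-band residue from auto-exposure /
#'   white-balance hunting and compression, independent per channel and
#'   region, present regardless of scene illumination.
#' @param amp_mod Depth of the slow pulse-amplitude modulation (0 disables);
#'   the color and motion sides get independent envelopes.
#' @param seed Integer seed; same seed, same outputs, bit for bit.
#' @param baseline_rgb Baseline skin color (R, G, B) in 8-bit units.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duration = 180, fps = 30, hr_bpm = 72,
                       pulse_amp_rgb = 0.2, pbv = default_pbv(),
                       bcg_amp = 0.35, illum_amp = 0.2,
                       illum_band = c(3, 8), motion_rate = 0,
                       motion_amp = 14, expression_fraction = 0,
                       jitter_px = 0.4, sensor_noise = 0.5,
                       resp_amp = 1.5, sway_px = 0.3, color_noise = 0.25,
                       amp_mod = 0.4, seed = 1L,
                       baseline_rgb = c(150, 110, 95)) {
  if (duration < 20) stop("sim_config: duration must be >= 20 s")
  if (fps < 10) stop("sim_config: fps must be >= 10")
  amps <- c(pulse_amp_rgb, bcg_amp, illum_amp, motion_amp, jitter_px,
            sensor_noise, resp_amp, sway_px, color_noise, amp_mod)
  if (any(amps < 0)) stop("sim_config: amplitudes must be >= 0")
  if (expression_fraction < 0 || expression_fraction > 1) {
    stop("sim_config: expression_fraction must be in [0, 1]")
  }
  cfg <- structure(list(duration = duration, fps = fps, hr_bpm = hr_bpm,
                        pulse_amp_rgb = pulse_amp_rgb, pbv = pbv,
                        bcg_amp = bcg_amp, illum_amp = illum_amp,
                        illum_band = illum_band, motion_rate = motion_rate,
                        motion_amp = motion_amp,
                        expression_fraction = expression_fraction,
                        jitter_px = jitter_px, sensor_noise = sensor_noise,
                        resp_amp = resp_amp, sway_px = sway_px,
                        color_noise = color_noise, amp_mod = amp_mod,
                        seed = as.integer(seed),
                        baseline_rgb = baseline_rgb),
                   class = "sim_config")
  hr_at(cfg, 0)  # validates the trajectory shape and range
  cfg
}

# Heart rate (bpm) at time(s) t for a config.
hr_at <- function(cfg, t) {
  hr <- cfg$hr_bpm
  out <- if (is.numeric(hr) && length(hr) == 1L) {
    rep(hr, length(t))
  } else {
    hr <- as.matrix(as.data.frame(hr))
    if (ncol(hr) != 2L) stop("sim_config: hr_bpm must be scalar or (time, bpm)")
    stats::approx(hr[, 1], hr[, 2], xout = t, rule = 2)$y
  }
  if (any(out < 45 | out > 150)) {
    stop("sim_config: heart rate outside 45-150 bpm")
  }
  out
}

#' Ground-truth heart-rate series of a configuration
#' @param cfg A [sim_config].
#' @return Data frame with columns `time` (s) and `bpm`.
#' @export
ground_truth <- function(cfg) {
  n <- round(cfg$duration * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  data.frame(time = t, bpm = hr_at(cfg, t))
}

#' Cardiac pulse waveform
#'
#' Unit-amplitude quasi-periodic waveform: a fundamental at `hr/60` Hz plus
#' a second harmonic at relative amplitude 0.3, with the instantaneous
#' frequency following the configured heart-rate trajectory via phase
#' integration.
#'
#' @param cfg A [sim_config].
#' @return A [signal1d] at the configured frame rate.
#' @export
pulse_waveform <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  hr <- hr_at(cfg, t)
  phase <- 2 * pi * cumsum(hr / 60) / cfg$fps
  signal1d(sin(phase) + 0.3 * sin(2 * phase), cfg$fps)
}

# Zero-mean, unit-sd noise band-limited to [flo, fhi] Hz (FFT shaping).
noise_bandlimited <- function(n, fs, flo, fhi) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[!(f >= flo & f <= fhi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Zero-mean, unit-sd narrowband interference whose instantaneous frequency
# performs a bounded random walk inside `band`, with a slowly varying
# amplitude envelope: emulates luminance reflected from changing screen or
# ambient content, the kind of structured noise that competes with the
# pulse peak inside the analysis band.
noise_wandering_tone <- function(n, fs, band) {
  steps <- stats::rnorm(n, sd = 0.5 / fs)  # ~0.5 Hz/s drift
  f <- stats::runif(1, band[1], band[2]) + cumsum(steps)
  f <- band[1] + abs((f - band[1]) %% (2 * (band[2] - band[1])) -
                       (band[2] - band[1]))  # reflect into the band
  phase <- 2 * pi * cumsum(f) / fs
  env <- 1 + 0.5 * noise_bandlimited(n, fs, 0.02, 0.1)
  y <- env * sin(phase + stats::runif(1, 0, 2 * pi))
  y / stats::sd(y)
}

# Zero-mean, unit-sd respiratory head-sway waveform. Breathing is
# quasi-periodic (rate wanders inside RESP_BAND) and asymmetric (inhale
# slower than exhale), so the waveform carries harmonics of the breath
# rate; the 3rd--5th harmonics fall inside the cardiac analysis band and
# are the classic narrowband confounder for motion-based pulse extraction.
noise_breathing <- function(n, fs) {
  steps <- stats::rnorm(n, sd = 0.15 / fs)  # breath-to-breath rate variation
  f <- stats::runif(1, RESP_BAND[1], RESP_BAND[2]) + cumsum(steps)
  w <- RESP_BAND[2] - RESP_BAND[1]
  f <- RESP_BAND[1] + abs((f - RESP_BAND[1]) %% (2 * w) - w)
  phase <- 2 * pi * cumsum(f) / fs + stats::runif(1, 0, 2 * pi)
  depth <- 1 + 0.4 * noise_bandlimited(n, fs, 0.01, 0.05)
  y <- depth * (sin(phase) + 0.45 * sin(2 * phase + 0.8) +
                  0.25 * sin(3 * phase + 1.6) + 0.12 * sin(4 * phase + 2.4) +
                  0.06 * sin(5 * phase + 3.2))
  y / stats::sd(y)
}

# Zero-mean, unit-sd 1/f ("pink") broadband noise.
noise_one_over_f <- function(n, fs) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  f[f <= 0] <- fs / n
  X <- X / sqrt(f)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate per-region RGB traces
#'
#' Each region's trace is baseline skin color plus the pulse along the PBV
#' direction plus illumination noise: a flicker component band-limited to
#' `illum_band` hitting the channels with warm-light gains, and a weaker
#' independent per-channel 1/f broadband floor. Noise realizations are
#' independent across regions.
#'
#' @param cfg A [sim_config].
#' @return List with `traces` (three [rgb_trace]s) and `truth`
#'   (the [ground_truth] data frame).
#' @export
simulate_rgb <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pulse <- pulse_waveform(cfg)$samples
  n <- length(pulse)
  labs <- c("nose", "left_cheek", "right_cheek")
  traces <- with_seed(derive_seed(cfg$seed, 101L), {
    env <- pulse_envelope(n, cfg$fps, cfg$amp_mod)
    lapply(labs, function(lab) {
      hf <- noise_bandlimited(n, cfg$fps, cfg$illum_band[1], cfg$illum_band[2])
      wander <- noise_wandering_tone(n, cfg$fps, ILLUM_WANDER_BAND)
      # the light's color drifts slowly (changing screen/ambient content),
      # so the channel gains are modulated around the warm-light baseline
      drift <- lapply(1:3, function(c) {
        1 + 0.6 * noise_bandlimited(n, cfg$fps, 0.01, 0.08)
      })
      ch <- lapply(1:3, function(c) {
        floor_c <- noise_one_over_f(n, cfg$fps)
        illum <- ILLUM_CHANNEL_GAIN[c] * drift[[c]] *
          (ILLUM_W_FLICKER * hf + ILLUM_W_WANDER * wander) +
          ILLUM_W_FLOOR * floor_c
        # in-band residue (auto-exposure / white-balance hunting,
        # compression) hits each channel independently, so no projection
        # direction can null it
        tone <- if (cfg$color_noise > 0) {
          cfg$color_noise * noise_wandering_tone(n, cfg$fps, COLOR_TONE_BAND)
        } else 0
        v <- cfg$baseline_rgb[c] +
          cfg$pbv[c] * cfg$pulse_amp_rgb * env * pulse +
          cfg$illum_amp * illum + tone +
          cfg$sensor_noise * stats::rnorm(n)
        pmin(pmax(v, 0), 255)
      })
      rgb_trace(lab, ch[[1]], ch[[2]], ch[[3]], cfg$fps)
    })
  })
  names(traces) <- labs
  list(traces = traces, truth = ground_truth(cfg))
}

# Shared (whole-head) transient motion: Poisson-arriving half-sine bumps of
# amplitude motion_amp, duration 0.5-2 s, random sign. Consumes the RNG.
motion_events <- function(cfg, t) {
  n <- length(t)
  m <- numeric(n)
  k <- stats::rpois(1L, cfg$motion_rate * cfg$duration / 60)
  if (k > 0 && cfg$motion_amp > 0) {
    onsets <- stats::runif(k, 0, cfg$duration)
    durs <- stats::runif(k, 0.5, 2)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    for (e in seq_len(k)) {
      idx <- which(t >= onsets[e] & t <= onsets[e] + durs[e])
      m[idx] <- m[idx] +
        signs[e] * cfg$motion_amp * sin(pi * (t[idx] - onsets[e]) / durs[e])
    }
  }
  m
}

#' Simulate tracked-point trajectories
#'
#' Produces the 80-point trajectory bank: each y-row is its grid baseline
#' plus the vertical ballistocardiographic oscillation
#' (`bcg_amp * pulse`), white tracking jitter, transient whole-head motion
#' events (shared across all points), and low-frequency expression
#' artifacts on a random subset of points.
#'
#' @param cfg A [sim_config].
#' @return List with `traj` (a [trajectory_bank]) and `truth`.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pulse <- pulse_waveform(cfg)$samples
  n <- length(pulse)
  t <- (seq_len(n) - 1) / cfg$fps
  face <- face_box(100, 60, 120, 140)
  rois <- compute_rois(face)
  grid <- make_point_grid(rois$forehead, rois$nose)
  np <- nrow(grid$points)
  traj <- with_seed(derive_seed(cfg$seed, 202L), {
    m <- motion_events(cfg, t)
    env <- pulse_envelope(n, cfg$fps, cfg$amp_mod)
    resp <- if (cfg$resp_amp > 0) {
      cfg$resp_amp * noise_breathing(n, cfg$fps)
    } else 0
    # tracker error has a common-mode 1/f component on top of the per-point
    # white jitter: appearance and lighting changes displace every point's
    # estimate together
    track_common <- if (cfg$jitter_px > 0) {
      cfg$jitter_px * noise_one_over_f(n, cfg$fps)
    } else 0
    # postural micro-sway: even "motionless" heads move at the sub-pixel
    # scale across the pulse band, the limiting noise for motion-based pulse
    sway <- if (cfg$sway_px > 0) {
      cfg$sway_px * noise_bandlimited(n, cfg$fps, SWAY_BAND[1], SWAY_BAND[2])
    } else 0
    shared <- cfg$bcg_amp * env * pulse + resp + m + track_common + sway
    ys <- matrix(rep(grid$points[, 2], times = n), np, n) +
      matrix(rep(shared, each = np), np, n) +
      matrix(stats::rnorm(np * n, sd = cfg$jitter_px), np, n)
    xs <- matrix(rep(grid$points[, 1], times = n), np, n) +
      matrix(stats::rnorm(np * n, sd = cfg$jitter_px), np, n)
    n_expr <- round(cfg$expression_fraction * np)
    if (n_expr > 0) {
      affected <- sample(np, n_expr)
      for (p in affected) {
        ys[p, ] <- ys[p, ] + EXPRESSION_SD *
          noise_bandlimited(n, cfg$fps, EXPRESSION_BAND[1], EXPRESSION_BAND[2])
      }
    }
    trajectory_bank(xs, ys, cfg$fps, region = grid$region)
  })
  list(traj = traj, truth = ground_truth(cfg))
}

#' Physiological heart-rate trajectory with variability
#'
#' Resting heart rate is not constant: autonomic regulation (including
#' respiratory sinus arrhythmia) makes it wander by a few beats per minute
#' over tens of seconds. This builds a piecewise-linear trajectory whose
#' breakpoint values follow a bounded random walk around `base`, suitable as
#' the `hr_bpm` field of [sim_config]. Deterministic given the seed.
#'
#' @param duration Trajectory length in seconds.
#' @param base Mean heart rate in bpm.
#' @param sd Step standard deviation per breakpoint, bpm.
#' @param max_dev Maximum deviation from `base`, bpm.
#' @param step_s Breakpoint spacing in seconds.
#' @param seed Integer seed.
#' @return Two-column matrix of (time, bpm) breakpoints.
#' @export
hrv_trajectory <- function(duration, base = 72, sd = 2, max_dev = 6,
                           step_s = 10, seed = 1L) {
  times <- seq(0, duration, by = step_s)
  dev <- with_seed(derive_seed(seed, 505L), {
    d <- cumsum(stats::rnorm(length(times), sd = sd))
    pmin(pmax(d, -max_dev), max_dev)
  })
  cbind(time = times, bpm = pmin(pmax(base + dev, 45), 150))
}

#' Scenario presets for the three study conditions
#'
#' `"normal"`: mild illumination only (stationary, expressionless sitter).
#' `"expressions"`: adds expression artifacts on 40% of points and
#' occasional head movements (2/min). `"hci"`: screen-driven illumination
#' (7.5x stronger), frequent movements (6/min), and expressions -- the
#' daily-life condition. Unless overridden, the heart rate follows a
#' seeded [hrv_trajectory] around 72 bpm rather than a constant, since a
#' perfectly steady sitter has a perfectly steady spectrum that no realistic
#' recording shows.
#'
#' @param name One of `"normal"`, `"expressions"`, `"hci"`.
#' @param ... Further arguments (e.g. `duration`, `seed`, `hr_bpm`) passed
#'   to [sim_config].
#' @return A [sim_config].
#' @export
scenario <- function(name, ...) {
  name <- match.arg(name, c("normal", "expressions", "hci"))
  preset <- switch(name,
    normal      = list(illum_amp = 0.2, motion_rate = 0,
                       expression_fraction = 0),
    expressions = list(illum_amp = 0.2, motion_rate = 2,
                       expression_fraction = 0.4),
    hci         = list(illum_amp = 1.5, motion_rate = 6,
                       expression_fraction = 0.4)
  )
  args <- utils::modifyList(preset, list(...))
  if (is.null(args$hr_bpm)) {
    dur <- if (is.null(args$duration)) 180 else args$duration
    sd0 <- if (is.null(args$seed)) 1L else args$seed
    args$hr_bpm <- hrv_trajectory(dur, seed = sd0)
  }
  do.call(sim_config, args)
}

#' Render a synthetic facial clip
#'
#' A flat skin-colored face rectangle with a static texture (so points are
#' trackable) whose vertical position follows the simulated head motion
#' (ballistocardiographic oscillation plus transient movement events) and
#' whose measurement regions carry the simulated RGB pulse modulation.
#' Frames are produced lazily through the `$frame(i)` accessor; true face
#' boxes are emitted per frame.
#'
#' @param cfg A [sim_config].
#' @param width,height Frame size in pixels.
#' @param jump_px,jump_frame Optional instantaneous vertical jump of
#'   `jump_px` pixels from frame `jump_frame` (1-based) on, for exercising
#'   the re-detection rule.
#' @return Object of class `synthetic_clip`: `frame(i)` returning an RGB
#'   array, `n_frames`, `fps`, `boxes` (per-frame face boxes), and the
#'   underlying `traces`, `traj`, and `truth`.
#' @export
render_clip <- function(cfg, width = 320L, height = 240L,
                        jump_px = 0, jump_frame = NA) {
  stopifnot(inherits(cfg, "sim_config"))
  rgb_sim <- simulate_rgb(cfg)
  n <- length(rgb_sim$traces$nose$r)
  t <- (seq_len(n) - 1) / cfg$fps
  pulse <- pulse_waveform(cfg)$samples
  fw <- 120L; fh <- 150L
  fx <- round((width - fw) / 2); fy <- round((height - fh) / 2)
  if (fy + fh + 30 > height || fy < 30) {
    stop("render_clip: frame too small for the face plus motion margin")
  }
  dy <- with_seed(derive_seed(cfg$seed, 303L),
                  cfg$bcg_amp * pulse + motion_events(cfg, t))
  if (!is.na(jump_frame)) {
    dy[seq_len(n) >= jump_frame] <- dy[seq_len(n) >= jump_frame] + jump_px
  }
  # trajectories consistent with the rendered motion (no jitter/expressions:
  # the renderer moves the whole head rigidly)
  rois0 <- compute_rois(face_box(fx, fy, fw, fh))
  grid0 <- make_point_grid(rois0$forehead, rois0$nose)
  np <- nrow(grid0$points)
  traj <- trajectory_bank(
    matrix(rep(grid0$points[, 1], times = n), np, n),
    matrix(rep(grid0$points[, 2], times = n), np, n) +
      matrix(rep(dy, each = np), np, n),
    cfg$fps, region = grid0$region)
  texture <- with_seed(derive_seed(cfg$seed, 404L), {
    tx <- array(0, c(fh, fw, 3))
    for (c in 1:3) {
      tx[, , c] <- cfg$baseline_rgb[c] + matrix(stats::runif(fh * fw, -12, 12),
                                                fh, fw)
    }
    tx
  })
  baseline <- cfg$baseline_rgb
  traces <- rgb_sim$traces
  frame_fun <- function(i) {
    fr <- array(60, c(height, width, 3))
    k <- floor(dy[i]); a <- dy[i] - k
    rows <- (fy + k + 1L):(fy + k + fh)
    cols <- (fx + 1L):(fx + fw)
    for (c in 1:3) {
      tc <- texture[, , c]
      tsh <- (1 - a) * tc + a * rbind(tc[1, , drop = FALSE],
                                      tc[-fh, , drop = FALSE])
      fr[rows, cols, c] <- tsh
    }
    box <- face_box(fx, fy + dy[i], fw, fh, frame_index = i - 1L)
    rs <- compute_rois(box)
    for (lab in c("nose", "left_cheek", "right_cheek")) {
      r <- rs[[lab]]
      rr <- (round_half_away(r$y0) + 1L):round_half_away(r$y1)
      cc <- (round_half_away(r$x0) + 1L):round_half_away(r$x1)
      tr <- traces[[lab]]
      offs <- c(tr$r[i], tr$g[i], tr$b[i]) - baseline
      for (c in 1:3) fr[rr, cc, c] <- fr[rr, cc, c] + offs[c]
    }
    pmin(pmax(fr, 0), 255)
  }
  boxes <- data.frame(frame_index = seq_len(n) - 1L,
                      x = fx, y = fy + dy, w = fw, h = fh)
  structure(list(frame = frame_fun, n_frames = n, fps = cfg$fps,
                 width = width, height = height, boxes = boxes,
                 traces = traces, traj = traj, truth = rgb_sim$truth),
            class = "synthetic_clip")
}

#' @export
print.synthetic_clip <- function(x, ...) {
  cat(sprintf("<synthetic_clip> %d frames %dx%d @ %g Hz\n",
              x$n_frames, x$width, x$height, x$fps))
  invisible(x)
}
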