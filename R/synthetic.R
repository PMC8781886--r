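#' Heart-rate trajectories for synthetic scenes
#'
#' A trajectory describes the instantaneous heart rate (bpm) over the
#' scene duration and must stay inside the 42-150 bpm pulse band.
#'
#' @param bpm,from,to,times,values trajectory parameters in bpm / seconds.
#' @return object of class `hr_trajectory`.
#' @name hr-trajectory
NULL

check_bpm <- function(b) {
  if (any(b < 42 | b > 150))
    stop("heart-rate trajectory must stay within 42-150 bpm")
  b
}

#' @rdname hr-trajectory
#' @export
hr_constant <- function(bpm) {
  check_bpm(bpm)
  structure(list(type = "constant", bpm = bpm), class = "hr_trajectory")
}

#' @rdname hr-trajectory
#' @export
hr_linear <- function(from, to) {
  check_bpm(c(from, to))
  structure(list(type = "linear", from = from, to = to),
            class = "hr_trajectory")
}

#' @rdname hr-trajectory
#' @export
hr_step <- function(times, values) {
  stopifnot(length(times) == length(values), times[1] == 0,
            !is.unsorted(times))
  check_bpm(values)
  structure(list(type = "step", times = times, values = values),
            class = "hr_trajectory")
}

#' Instantaneous heart rate of a trajectory
#'
#' @param traj an `hr_trajectory`.
#' @param t time(s) in seconds.
#' @param duration scene duration (needed to scale linear drifts).
#' @return bpm value(s) at `t`.
#' @export
hr_at <- function(traj, t, duration) {
  switch(traj$type,
         constant = rep(traj$bpm, length(t)),
         linear = traj$from + (traj$to - traj$from) * pmin(t / duration, 1),
         step = traj$values[findInterval(t, traj$times)],
         stop("unknown trajectory type"))
}

# Phase function phi(t) = 2*pi * integral of f(s) ds on a fine grid, plus a
# seeded random initial phase; returned as an interpolating function.
pulse_phase_fun <- function(traj, duration, seed) {
  set.seed(seed)
  phi0 <- stats::runif(1, 0, 2 * pi)
  fine <- 240
  tg <- seq(0, duration, by = 1 / fine)
  f <- hr_at(traj, tg, duration) / 60
  phi <- phi0 + 2 * pi * c(0, cumsum((f[-1] + f[-length(f)]) / 2)) / fine
  function(t) stats::approx(tg, phi, xout = t, rule = 2)$y
}

pulse_value <- function(phi) sin(phi) + 0.3 * sin(2 * phi)

#' Synthesise a quasi-periodic pulse waveform
#'
#' Phase-integrated oscillation (fundamental plus a 0.3-weighted second
#' harmonic, mimicking the systolic/dicrotic shape of a PPG) whose
#' instantaneous frequency follows the heart-rate trajectory. Deterministic
#' given `(trajectory, duration, rate, seed)`.
#'
#' @param traj an `hr_trajectory`.
#' @param duration duration in seconds.
#' @param rate sampling rate in Hz (60 for an oximeter-like reference).
#' @param seed RNG seed (sets the initial phase).
#' @return a [pulse_trace()].
#' @export
pulse_waveform <- function(traj, duration, rate = 60, seed = 1L) {
  phase <- pulse_phase_fun(traj, duration, seed)
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  pulse_trace(pulse_value(phase(t)), rate = rate, t0 = 0)
}

#' Scene configuration for the synthetic pulse-video generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' face-like skin region whose colour is additively modulated by a pulse
#' waveform with a green-dominant colour vector, per-pixel white noise,
#' slow global illumination drift, consistent 68-point landmarks with
#' detector-like jitter, and a 60 Hz reference trace. The default pulse
#' amplitude (2 intensity units on the 0-255 scale) against noise of
#' standard deviation 1 makes single-pixel recovery hopeless but spatial
#' pooling easy, which is the regime facial video lives in.
#'
#' @param duration_s scene length in seconds.
#' @param frame_rate video frame rate in Hz.
#' @param frame_size frame size `(H, W)` in pixels.
#' @param ppg_rate reference-trace sampling rate in Hz.
#' @param hr_trajectory an `hr_trajectory` within 42-150 bpm.
#' @param pulse_amplitude peak pulse modulation in intensity units (0-255).
#' @param noise_sd per-pixel, per-channel white-noise standard deviation.
#' @param illumination_drift list with `amplitude` (intensity units) and
#'   `period_s` of the global sinusoidal drift.
#' @param landmark_jitter_sd per-coordinate landmark jitter in pixels.
#' @param seed RNG seed; every random element derives from it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 12, frame_rate = 30,
                         frame_size = c(96L, 128L), ppg_rate = 60,
                         hr_trajectory = hr_constant(72),
                         pulse_amplitude = 2, noise_sd = 1,
                         illumination_drift = list(amplitude = 1,
                                                   period_s = 20),
                         landmark_jitter_sd = 0.5, seed = 1L) {
  stopifnot(duration_s > 0, frame_rate > 0, ppg_rate > 0,
            pulse_amplitude >= 0, noise_sd >= 0, landmark_jitter_sd >= 0)
  if (any(frame_size < 64L))
    stop("frame too small to contain the face layout (min 64 px per side)")
  structure(list(duration_s = duration_s, frame_rate = frame_rate,
                 frame_size = as.integer(frame_size), ppg_rate = ppg_rate,
                 hr_trajectory = hr_trajectory,
                 pulse_amplitude = pulse_amplitude, noise_sd = noise_sd,
                 illumination_drift = illumination_drift,
                 landmark_jitter_sd = landmark_jitter_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Canonical 68-point landmark template for a frame of size (H, W), 0-based
# pixel coordinates. The ten ROI-driving points are placed so that the
# cheek and forehead boxes always fall on the elliptical skin region.
landmark_template <- function(frame_size) {
  H <- frame_size[1]; W <- frame_size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  a <- 0.32 * W; b <- 0.42 * H
  p <- matrix(NA_real_, 68, 2)
  tj <- (0:16) / 16                                    # jaw 0-16
  p[1:17, 1] <- cx - a * cos(pi * tj)
  p[1:17, 2] <- cy + 0.9 * b * sin(pi * tj)
  p[18:22, 1] <- seq(cx - 0.22 * W, cx - 0.08 * W, length.out = 5)  # brows
  p[23:27, 1] <- seq(cx + 0.08 * W, cx + 0.22 * W, length.out = 5)
  p[18:27, 2] <- cy - 0.14 * H
  p[28:36, 1] <- cx                                    # nose 27-35
  p[28:36, 2] <- seq(cy - 0.10 * H, cy + 0.08 * H, length.out = 9)
  eye <- function(ecx) {                               # 36-41 / 42-47
    ang <- c(180, 120, 60, 0, 300, 240) * pi / 180
    cbind(ecx + 0.05 * W * cos(ang), cy - 0.07 * H - 0.02 * H * sin(ang))
  }
  p[37:42, ] <- eye(cx - 0.15 * W)
  p[43:48, ] <- eye(cx + 0.15 * W)
  mang <- seq(180, -150, by = -30) * pi / 180          # outer mouth 48-59
  mcx <- cx; mcy <- cy + 0.21 * H
  p[49:60, ] <- cbind(mcx + 0.08 * W * cos(mang), mcy - 0.03 * H * sin(mang))
  iang <- seq(180, -135, by = -45) * pi / 180          # inner mouth 60-67
  p[61:68, ] <- cbind(mcx + 0.05 * W * cos(iang), mcy - 0.015 * H * sin(iang))
  colnames(p) <- c("x", "y")
  p
}

# Logical (H, W) mask of the elliptical skin region matching the template.
skin_mask <- function(frame_size) {
  H <- frame_size[1]; W <- frame_size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  a <- 0.32 * W; b <- 0.42 * H
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

#' Render a synthetic pulse-video scene
#'
#' @param config a [scene_config()].
#' @return object of class `synthetic_scene` with `frames`
#'   (`(T, H, W, 3)` array, 0-255 intensity scale), `landmarks` (list of
#'   [landmark_set()]), `reference` (the ground-truth [pulse_trace()] at
#'   `ppg_rate`), `true_hr` (an `hr_series` of the configured trajectory in
#'   10 s / 2 s windows), the skin `mask` and the `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$frame_size[1]; W <- config$frame_size[2]
  fps <- config$frame_rate
  n <- round(config$duration_s * fps)
  phase <- pulse_phase_fun(config$hr_trajectory, config$duration_s,
                           config$seed)
  frame_times <- (seq_len(n) - 1) / fps
  wave_f <- pulse_value(phase(frame_times))
  tref <- seq(0, config$duration_s - 1 / config$ppg_rate,
              by = 1 / config$ppg_rate)
  reference <- pulse_trace(pulse_value(phase(tref)), rate = config$ppg_rate,
                           t0 = 0)

  mask <- skin_mask(config$frame_size)
  base <- array(60, c(H, W, 3))
  skin_col <- c(180, 120, 100)
  for (c in 1:3) {
    ch <- base[, , c]
    ch[mask] <- skin_col[c]
    base[, , c] <- ch
  }
  colvec <- c(0.5, 1, 0.5)                 # green carries twice the pulse
  drift <- config$illumination_drift
  drift_t <- drift$amplitude * sin(2 * pi * frame_times / drift$period_s)

  set.seed(config$seed + 1L)               # pixel noise + landmark jitter
  frames <- array(0, c(n, H, W, 3))
  for (i in seq_len(n)) {
    img <- base
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- ch[mask] + config$pulse_amplitude * wave_f[i] * colvec[c]
      img[, , c] <- ch + drift_t[i]
    }
    if (config$noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = config$noise_sd)
    frames[i, , , ] <- pmin(pmax(img, 0), 255)
  }

  tmpl <- landmark_template(config$frame_size)
  landmarks <- lapply(seq_len(n) - 1L, function(i) {
    jit <- if (config$landmark_jitter_sd > 0)
      matrix(stats::rnorm(136, sd = config$landmark_jitter_sd), 68, 2)
    else matrix(0, 68, 2)
    landmark_set(tmpl + jit, frame_index = i)
  })

  true_hr <- trajectory_hr_series(config$hr_trajectory, config$duration_s)
  structure(list(frames = frames, landmarks = landmarks,
                 reference = reference, true_hr = true_hr, mask = mask,
                 frame_times = frame_times, config = config),
            class = "synthetic_scene")
}

# Ground-truth windowed HR: the trajectory averaged over each 10 s window.
trajectory_hr_series <- function(traj, duration, window = 10, step = 2) {
  if (duration < window)
    return(hr_series(data.frame(start_s = numeric(0), end_s = numeric(0),
                                bpm = numeric(0))))
  starts <- seq(0, duration - window, by = step)
  bpm <- vapply(starts, function(s) {
    tt <- seq(s, s + window, length.out = 201)
    mean(hr_at(traj, tt, duration))
  }, numeric(1))
  hr_series(data.frame(start_s = starts, end_s = starts + window, bpm = bpm))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("synthetic_scene: %d frames of %dx%d @ %g fps, reference @ %g Hz\n",
              d[1], d[2], d[3], x$config$frame_rate, x$config$ppg_rate))
  invisible(x)
}

#' Classical spatial-mean heart-rate baseline
#'
#' Averages the green channel over the true skin region frame by frame,
#' band-passes the resulting trace and estimates windowed heart rates.
#' Recovering the configured trajectory this way validates the generator
#' independently of any network.
#'
#' @param scene a `synthetic_scene`.
#' @return an `hr_series`.
#' @export
baseline_green_hr <- function(scene) {
  n <- dim(scene$frames)[1]
  g <- vapply(seq_len(n), function(i) mean(scene$frames[i, , , 2][scene$mask]),
              numeric(1))
  tr <- pulse_trace(g, rate = scene$config$frame_rate, t0 = 0)
  windowed_hr(bandpass(tr))
}

#' Write a scene to disk
#'
#' Produces the on-disk layout the pipeline consumes: zero-padded
#' `%06d.png` frames, `landmarks.csv` in the dialect of
#' [parse_landmarks()], `reference.txt` (one sample per line), and
#' `scene.yaml` with the full configuration (including the sampling rates).
#'
#' @param scene a `synthetic_scene`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frames_dir <- file.path(out_dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  n <- dim(scene$frames)[1]
  for (i in seq_len(n)) {
    png::writePNG(scene$frames[i, , , ] / 255,
                  file.path(frames_dir, sprintf("%06d.png", i - 1L)))
  }
  write_landmarks(scene$landmarks, file.path(out_dir, "landmarks.csv"))
  writeLines(format(scene$reference$samples, digits = 10),
             file.path(out_dir, "reference.txt"))
  cfg <- scene$config
  cfg$hr_trajectory <- unclass(cfg$hr_trajectory)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "scene.yaml"))
  invisible(out_dir)
}

#' Read a frame directory into an array
#'
#' @param frames_dir directory of `%06d.png` frames.
#' @return `(T, H, W, 3)` array on the 0-255 intensity scale.
#' @export
read_frames <- function(frames_dir) {
  files <- sort(list.files(frames_dir, pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", frames_dir)
  first <- png::readPNG(files[1])
  d <- dim(first)
  frames <- array(0, c(length(files), d[1], d[2], 3))
  frames[1, , , ] <- first[, , 1:3] * 255
  for (i in seq_along(files)[-1])
    frames[i, , , ] <- png::readPNG(files[i])[, , 1:3] * 255
  frames
}

#' Read a reference trace written by [write_scene()]
#'
#' @param path `reference.txt` file.
#' @param rate sampling rate in Hz (from the scene YAML).
#' @return a [pulse_trace()].
#' @export
read_reference <- function(path, rate) {
  pulse_trace(as.numeric(readLines(path)), rate = rate, t0 = 0)
}
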