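# Synthetic insole recordings with known step boundaries.
#
# The generator emulates the structure the preprocessing assumes: left-foot
# pressure alternating swing (all 8 channels zero) and stance (heel-to-toe
# activation of quantized levels), a right foot shifted by half a step,
# class-dependent periodic accel/gyro waveforms, and the single-sensor
# swing-phase artifact. It makes no claim of biomechanical fidelity.

#' Simulator configuration
#'
#' Defaults define the study conditions used throughout the package's tests
#' and examples. Per-class mean step durations (frames at 100 Hz) are
#' field-realistic round numbers: ~1 s for level walking, shorter for faster
#' gaits, longer for ascent. Stance occupies ~60% of the cycle for level
#' walking, less when running. Accel/gyro waveforms are sums of
#' `n_harmonics` sinusoids per step cycle whose per-class amplitude mixes
#' (rows of `class_harmonics`) and phase offsets separate the seven classes;
#' Gaussian sensor noise with `noise_sd` is added. The swing artifact
#' defaults to probability 0.05 per swing frame on left-foot channel 3, the
#' sensor reported to misread during swing.
#'
#' @param step_duration_mean named numeric vector, mean step length in frames
#'   per gait type.
#' @param step_duration_sd per-step truncated-Gaussian jitter (frames).
#' @param stance_fraction named numeric vector in (0,1), fraction of the step
#'   spent in stance.
#' @param pressure_template data frame with columns `sensor` (1..8), `onset`,
#'   `offset` (fractions of the stance), `level` (1 or 2).
#' @param accel_amplitude,gyro_amplitude base waveform amplitudes.
#' @param n_harmonics harmonics per step cycle.
#' @param class_harmonics 7 x n_harmonics amplitude-mix matrix (rows ordered
#'   as [gait_types()]).
#' @param class_phase per-class phase offset (radians).
#' @param noise_sd accel/gyro Gaussian noise standard deviation.
#' @param artifact_prob probability of the swing-phase noise artifact per
#'   swing frame, in `[0,1]`.
#' @param artifact_channel left-foot pressure channel affected (1..8).
#' @param tail_frames all-zero pressure frames appended after the final
#'   stance so the last step is demonstrably complete.
#' @return an object of class `gait_sim_config`.
#' @export
simulator_config <- function(
    step_duration_mean = c(walking = 105, fast_walking = 85, running = 68,
                           stair_climbing = 115, stair_descending = 95,
                           hill_climbing = 110, hill_descending = 100),
    step_duration_sd = 6,
    stance_fraction = c(walking = 0.62, fast_walking = 0.58, running = 0.45,
                        stair_climbing = 0.64, stair_descending = 0.60,
                        hill_climbing = 0.63, hill_descending = 0.61),
    pressure_template = default_pressure_template(),
    accel_amplitude = 1.0,
    gyro_amplitude = 0.8,
    n_harmonics = 3L,
    class_harmonics = default_class_harmonics(),
    class_phase = seq(0, by = 0.7, length.out = 7),
    noise_sd = 0.1,
    artifact_prob = 0.05,
    artifact_channel = 3L,
    tail_frames = 12L) {
  cfg <- structure(list(
    step_duration_mean = step_duration_mean, step_duration_sd = step_duration_sd,
    stance_fraction = stance_fraction, pressure_template = pressure_template,
    accel_amplitude = accel_amplitude, gyro_amplitude = gyro_amplitude,
    n_harmonics = as.integer(n_harmonics), class_harmonics = class_harmonics,
    class_phase = class_phase, noise_sd = noise_sd,
    artifact_prob = artifact_prob, artifact_channel = as.integer(artifact_channel),
    tail_frames = as.integer(tail_frames)), class = "gait_sim_config")
  abort_if(any(cfg$step_duration_mean < 4), "step durations must be >= 4 frames")
  abort_if(!all(names(step_duration_mean) %in% gait_types()) ||
             !all(gait_types() %in% names(step_duration_mean)),
           "step_duration_mean must be named by the 7 gait types")
  abort_if(any(cfg$stance_fraction <= 0 | cfg$stance_fraction >= 1),
           "stance_fraction must lie strictly in (0, 1)")
  abort_if(cfg$artifact_prob < 0 || cfg$artifact_prob > 1,
           "artifact_prob must lie in [0, 1]")
  abort_if(cfg$artifact_channel < 1 || cfg$artifact_channel > 8,
           "artifact_channel must be a left-foot channel 1..8")
  abort_if(!all(cfg$pressure_template$level %in% c(1, 2)),
           "pressure template peak levels must be 1 or 2")
  abort_if(nrow(cfg$class_harmonics) != 7 || ncol(cfg$class_harmonics) != cfg$n_harmonics,
           "class_harmonics must be 7 x n_harmonics")
  cfg
}

# Heel-strike to toe-off activation windows, as fractions of the stance:
# heel sensors fire at stance onset (>= 2 active channels at the stance
# start), forefoot from ~0.3, toes from ~0.5 through toe-off.
default_pressure_template <- function() {
  data.frame(
    sensor = 1:8,
    onset  = c(0.00, 0.00, 0.05, 0.30, 0.30, 0.35, 0.50, 0.50),
    offset = c(0.55, 0.60, 0.65, 0.85, 0.90, 0.90, 1.00, 1.00),
    level  = c(2L, 2L, 1L, 1L, 2L, 1L, 2L, 1L)
  )
}

# Distinct per-class harmonic amplitude mixes (rows: gait types in order).
default_class_harmonics <- function() {
  m <- rbind(
    walking          = c(1.0, 0.30, 0.10),
    fast_walking     = c(1.2, 0.55, 0.15),
    running          = c(1.8, 0.90, 0.40),
    stair_climbing   = c(0.9, 0.60, 0.30),
    stair_descending = c(1.1, 0.40, 0.55),
    hill_climbing    = c(1.0, 0.75, 0.20),
    hill_descending  = c(1.3, 0.20, 0.35)
  )
  m
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat(sprintf("<gait_sim_config> noise_sd=%g, artifact p=%g on channel %d\n",
              x$noise_sd, x$artifact_prob, x$artifact_channel))
  invisible(x)
}

#' Simulate one labeled insole recording with ground-truth boundaries
#'
#' Left-foot pressure alternates a swing phase (all channels zero) and a
#' stance phase following the heel-to-toe activation template; the right foot
#' carries the same pattern shifted by half a mean step. Accel and gyro
#' channels are class-dependent harmonic waveforms at the per-step cycle
#' frequency plus Gaussian noise. The returned ground truth lists the exact
#' swing/stance starts and half-open step intervals. Identical inputs yield
#' bitwise-identical output. No artifact noise is injected here; see
#' [inject_swing_noise()].
#'
#' @param config a `gait_sim_config`.
#' @param label gait type name.
#' @param n_steps number of unit steps (>= 1).
#' @param seed integer seed.
#' @param subject_id subject identifier stored in the recording.
#' @return list with `recording` (a `gait_recording`) and `truth` (class
#'   `gait_ground_truth`: `swing_starts`, `stance_starts`, `step_starts`,
#'   `step_ends`, `label`).
#' @export
simulate_recording <- function(config, label, n_steps, seed, subject_id = "sim") {
  abort_if(!inherits(config, "gait_sim_config"), "config must come from simulator_config()")
  abort_if(n_steps < 1, "n_steps must be >= 1")
  label <- match.arg(label, gait_types())
  code <- gait_label_code(label)
  with_seed(seed, {
    dur_mean <- config$step_duration_mean[[label]]
    durs <- pmax(4, round(stats::rnorm(n_steps, dur_mean, config$step_duration_sd)))
    sfrac <- config$stance_fraction[[label]]
    swing_len <- as.integer(pmax(2, round(durs * (1 - sfrac))))
    stance_len <- as.integer(pmax(2, durs - swing_len))
    durs <- swing_len + stance_len
    total <- sum(durs) + config$tail_frames

    step_starts <- cumsum(c(1L, durs[-n_steps]))
    stance_starts <- step_starts + swing_len
    step_ends <- step_starts + durs          # half-open [start, end)

    left <- matrix(0L, total, 8)
    tpl <- config$pressure_template
    for (i in seq_len(n_steps)) {
      sl <- stance_len[i]
      frac <- (seq_len(sl) - 1) / sl
      for (j in seq_len(nrow(tpl))) {
        on <- frac >= tpl$onset[j] & frac < tpl$offset[j]
        left[stance_starts[i] + which(on) - 1L, tpl$sensor[j]] <- tpl$level[j]
      }
      # guarantee >= 2 active channels on the stance-start frame and a
      # non-zero final stance frame (template already provides both, but a
      # 2-frame stance can defeat the fractions)
      if (sum(left[stance_starts[i], ] != 0) < 2) left[stance_starts[i], 1:2] <- 2L
      if (all(left[step_ends[i] - 1L, ] == 0)) left[step_ends[i] - 1L, 7:8] <- c(2L, 1L)
    }
    shift <- max(1L, round(dur_mean / 2))
    right <- left[c((shift + 1L):total, 1L:shift), , drop = FALSE]
    pressure <- cbind(left, right)

    # step-cycle phase tau in [0,1) per frame; the tail continues the rhythm
    tau <- numeric(total)
    for (i in seq_len(n_steps)) {
      idx <- step_starts[i]:(step_ends[i] - 1L)
      tau[idx] <- (seq_along(idx) - 1) / durs[i]
    }
    if (config$tail_frames > 0) {
      idx <- (total - config$tail_frames + 1L):total
      tau[idx] <- (seq_along(idx) - 1) / dur_mean
    }
    amps <- config$class_harmonics[code + 1L, ]
    phase0 <- config$class_phase[code + 1L]
    chan_scale <- c(1, 0.8, 0.6)
    chan_phase <- c(0, 0.5, 1.0)
    wave <- function(base_amp, harm_phase_shift) {
      m <- matrix(0, total, 6)
      for (ch in 1:6) {
        foot_phase <- if (ch <= 3) 0 else pi   # right foot half a cycle out
        ax <- ((ch - 1) %% 3) + 1
        sig <- 0
        for (h in seq_len(config$n_harmonics)) {
          sig <- sig + amps[h] * sin(2 * pi * h * tau + phase0 +
                                       chan_phase[ax] + harm_phase_shift * h + foot_phase)
        }
        m[, ch] <- base_amp * chan_scale[ax] * sig +
          stats::rnorm(total, 0, config$noise_sd)
      }
      m
    }
    accel <- wave(config$accel_amplitude, 0)
    gyro <- wave(config$gyro_amplitude, 0.9)

    truth <- structure(list(swing_starts = step_starts,
                            stance_starts = stance_starts,
                            step_starts = step_starts,
                            step_ends = step_ends,
                            label = rep(label, n_steps)),
                       class = "gait_ground_truth")
    list(recording = gait_recording(pressure, accel, gyro, label = label,
                                    subject_id = subject_id),
         truth = truth)
  })
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> %d step(s), label(s): %s\n",
              length(x$step_starts), paste(unique(x$label), collapse = ", ")))
  invisible(x)
}

#' Inject the swing-phase noise artifact into a recording
#'
#' Sets the given left-foot pressure channel to 1, independently with
#' probability `p`, on every frame of every true swing interval
#' `[swing_start, stance_start)`. Stance frames are never modified.
#'
#' @param recording a `gait_recording`.
#' @param truth the `gait_ground_truth` for `recording`.
#' @param p artifact probability per swing frame.
#' @param channel left-foot channel index (1..8).
#' @param seed integer seed.
#' @return list with `recording` (noisy copy) and `n_injected` (frame count).
#' @export
inject_swing_noise <- function(recording, truth, p, channel = 3L, seed = 1L) {
  abort_if(p < 0 || p > 1, "p must lie in [0, 1]")
  abort_if(channel < 1 || channel > 8, "channel must be a left-foot channel 1..8")
  swing_frames <- unlist(lapply(seq_along(truth$swing_starts), function(i) {
    truth$swing_starts[i]:(truth$stance_starts[i] - 1L)
  }))
  with_seed(seed, {
    hit <- swing_frames[stats::runif(length(swing_frames)) < p]
    recording$pressure[hit, channel] <- 1L
    list(recording = recording, n_injected = length(hit))
  })
}

#' Simulate a balanced multi-class dataset
#'
#' Generates `n_per_class` recordings for each of the 7 gait types with
#' deterministically derived per-recording seeds, and injects the swing
#' artifact at the configured probability so the preprocessing pipeline is
#' exercised under realistic sensor faults. Set `artifact_prob = 0` in the
#' config for artifact-free data.
#'
#' @param config a `gait_sim_config`.
#' @param n_per_class recordings per gait type (>= 1).
#' @param steps_per_recording unit steps per recording (>= 1).
#' @param seed master integer seed.
#' @return list with `recordings` (length `7 * n_per_class`) and `truths`
#'   (matching `gait_ground_truth`s).
#' @export
simulate_dataset <- function(config, n_per_class, steps_per_recording, seed) {
  abort_if(n_per_class < 1 || steps_per_recording < 1, "counts must be >= 1")
  n_rec <- 7L * n_per_class
  seeds <- derive_seeds(seed, 2L * n_rec)
  recordings <- vector("list", n_rec)
  truths <- vector("list", n_rec)
  i <- 0L
  for (label in gait_types()) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      sim <- simulate_recording(config, label, steps_per_recording, seed = seeds[i],
                                subject_id = sprintf("sim_%s_%02d", label, r))
      if (config$artifact_prob > 0) {
        noisy <- inject_swing_noise(sim$recording, sim$truth,
                                    p = config$artifact_prob,
                                    channel = config$artifact_channel,
                                    seed = seeds[n_rec + i])
        sim$recording <- noisy$recording
      }
      recordings[[i]] <- sim$recording
      truths[[i]] <- sim$truth
    }
  }
  list(recordings = recordings, truths = truths)
}

#' Write a ground-truth sidecar file
#'
#' @param truth a `gait_ground_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(step = seq_along(truth$step_starts),
                   swing_start = truth$swing_starts,
                   stance_start = truth$stance_starts,
                   end = truth$step_ends,
                   label = truth$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar file
#'
#' @param path CSV path written by [write_ground_truth()].
#' @return a `gait_ground_truth`.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(swing_starts = df$swing_start, stance_starts = df$stance_start,
                 step_starts = df$swing_start, step_ends = df$end,
                 label = df$label),
            class = "gait_ground_truth")
}
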