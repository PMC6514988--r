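# Shared fixtures, built in code. Expensive objects are memoized for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

# Build a 16-column pressure matrix from a list of left-foot rows
# (each a length-8 vector); right foot stays zero.
pressure_from_left <- function(left_rows) {
  p <- matrix(0L, length(left_rows), 16)
  for (i in seq_along(left_rows)) p[i, 1:8] <- as.integer(left_rows[[i]])
  p
}

# A recording wrapper around an arbitrary pressure matrix with inert
# accel/gyro channels.
recording_from_pressure <- function(pressure, label = "walking") {
  n <- nrow(pressure)
  gait_recording(pressure,
                 accel = matrix(seq_len(n * 6) / 10, n, 6),
                 gyro = matrix(-seq_len(n * 6) / 20, n, 6),
                 label = label)
}

# Small balanced dataset (2 recordings x 25 steps per class, default
# simulator with artifact injection): 350 k=1 samples after preprocessing.
small_dataset <- function() {
  if (is.null(.fixture_cache$small)) {
    ds <- simulate_dataset(simulator_config(), n_per_class = 2,
                           steps_per_recording = 25, seed = 424242)
    .fixture_cache$small <- preprocess_recordings(ds$recordings, k = 1, t = 63)
  }
  .fixture_cache$small
}

# One standardized train/test split of the small dataset, reused by the
# model tests.
small_split <- function() {
  if (is.null(.fixture_cache$split)) {
    samples <- small_dataset()
    idx <- split_random_subsample(n_samples(samples), 250, 100,
                                  repetitions = 1, seed = 99)[[1]]
    .fixture_cache$split <- standardize_samples(subset_samples(samples, idx$train),
                                                subset_samples(samples, idx$test))
  }
  .fixture_cache$split
}

step_starts_of <- function(steps) vapply(steps, function(s) s$start, integer(1))
step_ends_of <- function(steps) vapply(steps, function(s) s$end, integer(1))

truth_annotation <- function(truth) {
  structure(list(swing_starts = truth$swing_starts,
                 stance_starts = truth$stance_starts,
                 foot = "left", n_frames = NA_integer_),
            class = "gait_phase_annotation")
}
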