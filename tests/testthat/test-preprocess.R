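# Phase detection, swing-noise cleaning, segmentation, normalization,
# flattening, sample assembly and standardization.

test_that("phase boundaries follow the zero-sum / two-sensor scanning rule", {
  # left-foot sums 3,2,0,0,0,0,2,3 with >= 2 active channels in the
  # trailing stance: swing starts at frame 3, stance at frame 7
  p <- pressure_from_left(list(c(2, 1, 0, 0, 0, 0, 0, 0),
                               c(1, 1, 0, 0, 0, 0, 0, 0),
                               rep(0, 8), rep(0, 8), rep(0, 8), rep(0, 8),
                               c(1, 1, 0, 0, 0, 0, 0, 0),
                               c(2, 1, 0, 0, 0, 0, 0, 0)))
  ann <- detect_phase_boundaries(p)
  expect_identical(ann$swing_starts, 3L)
  expect_identical(ann$stance_starts, 7L)

  # sums 0,0,2,2,0,0,3,3: two swing/stance pairs
  p2 <- pressure_from_left(list(rep(0, 8), rep(0, 8),
                                c(1, 1, 0, 0, 0, 0, 0, 0),
                                c(1, 1, 0, 0, 0, 0, 0, 0),
                                rep(0, 8), rep(0, 8),
                                c(2, 1, 0, 0, 0, 0, 0, 0),
                                c(2, 1, 0, 0, 0, 0, 0, 0)))
  ann2 <- detect_phase_boundaries(p2)
  expect_identical(ann2$swing_starts, c(1L, 5L))
  expect_identical(ann2$stance_starts, c(3L, 7L))
})

test_that("a lone single-sensor frame does not open a stance phase", {
  # swing interrupted by a channel-3 artifact: still one swing, one stance
  p <- pressure_from_left(list(c(1, 1, rep(0, 6)),
                               rep(0, 8),
                               c(0, 0, 1, rep(0, 5)),   # artifact, sum 1
                               rep(0, 8),
                               c(1, 1, rep(0, 6))))
  ann <- detect_phase_boundaries(p)
  expect_identical(ann$swing_starts, 2L)
  expect_identical(ann$stance_starts, 5L)
})

test_that("all-zero pressure yields one unpaired swing start and no steps", {
  p <- matrix(0L, 6, 16)
  ann <- detect_phase_boundaries(p)
  expect_identical(ann$swing_starts, 1L)
  expect_identical(ann$stance_starts, integer(0))
  expect_identical(segment_unit_steps(recording_from_pressure(p)), list())
})

test_that("swing-noise reduction zeroes exactly the sum-1 swing frames", {
  # stance | swing with artifact (frame 4, channel 3) | stance
  p <- pressure_from_left(list(c(1, 1, rep(0, 6)),
                               c(1, 1, rep(0, 6)),
                               rep(0, 8),
                               c(0, 0, 1, rep(0, 5)),
                               rep(0, 8),
                               c(2, 1, rep(0, 6)),
                               c(2, 1, rep(0, 6))))
  ann <- detect_phase_boundaries(p)
  out <- reduce_swing_noise(p, ann)
  expect_identical(out$corrections, 1L)
  expect_identical(out$pressure[4, 3], 0L)
  out$pressure[4, 3] <- 1L
  expect_identical(out$pressure, p)   # nothing else touched

  # noise-free input is returned unchanged
  q <- pressure_from_left(list(c(1, 1, rep(0, 6)), rep(0, 8), rep(0, 8),
                               c(1, 1, rep(0, 6))))
  clean <- reduce_swing_noise(q, detect_phase_boundaries(q))
  expect_identical(clean$corrections, 0L)
  expect_identical(clean$pressure, q)
})

test_that("a single sensor at level 2 during swing is not treated as noise", {
  p <- pressure_from_left(list(c(1, 1, rep(0, 6)),
                               rep(0, 8),
                               c(0, 0, 2, rep(0, 5)),   # sum 2: rule must not fire
                               rep(0, 8),
                               c(1, 1, rep(0, 6))))
  out <- reduce_swing_noise(p, detect_phase_boundaries(p))
  expect_identical(out$corrections, 0L)
  expect_identical(out$pressure, p)
})

test_that("segmentation recovers the simulator's exact step boundaries", {
  cfg <- simulator_config()
  for (label in c("walking", "running", "stair_descending")) {
    sim <- simulate_recording(cfg, label, n_steps = 6, seed = 101)
    steps <- segment_unit_steps(sim$recording)
    expect_length(steps, 6)
    expect_identical(step_starts_of(steps), sim$truth$step_starts)
    expect_identical(step_ends_of(steps), sim$truth$step_ends)
    expect_true(all(vapply(steps, function(s) s$label, "") == label))
  }
})

test_that("segmentation is exact after cleaning artifact-injected recordings", {
  cfg <- simulator_config()
  for (seed in c(5, 17)) {
    sim <- simulate_recording(cfg, "fast_walking", n_steps = 8, seed = seed)
    noisy <- inject_swing_noise(sim$recording, sim$truth, p = cfg$artifact_prob,
                                channel = cfg$artifact_channel, seed = seed + 1)
    expect_gt(noisy$n_injected, 0)
    steps <- segment_unit_steps(noisy$recording)
    expect_identical(step_starts_of(steps), sim$truth$step_starts)
    expect_identical(step_ends_of(steps), sim$truth$step_ends)
  }
})

test_that("segmentation is idempotent and conserves frames without overlap", {
  sim <- simulate_recording(simulator_config(), "hill_climbing", n_steps = 7, seed = 3)
  noisy <- inject_swing_noise(sim$recording, sim$truth, p = 0.05, seed = 4)$recording
  steps <- segment_unit_steps(noisy)

  # idempotence: segmenting the cleaned recording yields identical steps
  cleaned <- noisy
  cleaned$pressure <- reduce_swing_noise(noisy$pressure,
                                         detect_phase_boundaries(noisy$pressure))$pressure
  steps2 <- segment_unit_steps(cleaned)
  expect_identical(step_starts_of(steps2), step_starts_of(steps))
  expect_identical(lapply(steps2, `[[`, "pressure"), lapply(steps, `[[`, "pressure"))

  # conservation: steps tile [first swing start, last step end) exactly
  starts <- step_starts_of(steps); ends <- step_ends_of(steps)
  expect_identical(starts[-1], ends[-length(ends)])
  expect_identical(sum(vapply(steps, function(s) s$L, integer(1))),
                   ends[length(ends)] - starts[1])
})

test_that("a recording truncated mid-stance drops its final step", {
  sim <- simulate_recording(simulator_config(), "walking", n_steps = 4, seed = 21)
  rec <- sim$recording
  cut <- sim$truth$stance_starts[4] + 1L   # stop inside the 4th stance
  rec$pressure <- rec$pressure[1:cut, , drop = FALSE]
  rec$accel <- rec$accel[1:cut, , drop = FALSE]
  rec$gyro <- rec$gyro[1:cut, , drop = FALSE]
  steps <- segment_unit_steps(rec)
  expect_length(steps, 3)
})

test_that("normalize_step resamples channels and preserves the value domain", {
  sim <- simulate_recording(simulator_config(), "walking", n_steps = 3, seed = 8)
  steps <- segment_unit_steps(sim$recording)

  # identity when L == t
  s63 <- steps[[1]]
  idx63 <- seq_len(63)
  s63$pressure <- s63$pressure[idx63, ]; s63$accel <- s63$accel[idx63, ]
  s63$gyro <- s63$gyro[idx63, ]; s63$L <- 63L
  ns <- normalize_step(s63, 63)
  expect_identical(ns$pressure, s63$pressure)
  expect_equal(ns$accel, s63$accel, tolerance = 1e-12)

  # arbitrary L -> t x W arrays with quantized pressure
  ns2 <- normalize_step(steps[[2]], 63)
  expect_identical(dim(ns2$pressure), c(63L, 16L))
  expect_identical(dim(ns2$accel), c(63L, 6L))
  expect_true(all(ns2$pressure %in% 0:2))

  # constant channels stay constant under interpolation
  s <- steps[[3]]
  s$accel[, 2] <- 1.5
  expect_equal(normalize_step(s, 63)$accel[, 2], rep(1.5, 63), tolerance = 1e-12)

  s$L <- 1L
  expect_error(normalize_step(s, 63), "degenerate")
})

test_that("flattening is time-major, has the documented lengths, and inverts", {
  sim <- simulate_recording(simulator_config(), "running", n_steps = 2, seed = 9)
  ns <- normalize_step(segment_unit_steps(sim$recording)[[1]], 63)
  fl <- flatten_step(ns)
  expect_length(fl$pressure_vec, 1008)
  expect_length(fl$accel_vec, 378)
  expect_length(fl$gyro_vec, 378)
  expect_identical(fl$pressure_vec[1:16], as.vector(ns$pressure[1, ]))
  expect_equal(unflatten_step_vector(fl$accel_vec, 6), ns$accel, tolerance = 0)
})

test_that("k-step assembly windows are non-overlapping with remainder loss", {
  sim <- simulate_recording(simulator_config(), "walking", n_steps = 10, seed = 13)
  steps <- lapply(segment_unit_steps(sim$recording), normalize_step, t = 63)
  expect_identical(n_samples(assemble_samples(steps, k = 2)), 5L)
  expect_identical(n_samples(assemble_samples(steps, k = 3)), 3L)
  s3 <- assemble_samples(steps, k = 3)
  expect_identical(dim(s3$pressure)[2:3], c(189L, 16L))
  expect_identical(dim(s3$accel)[2:3], c(189L, 6L))
  # first sample stacks steps 1..3 in order
  expect_equal(s3$accel[1, 1:63, ], steps[[1]]$accel, tolerance = 0)
  expect_equal(s3$accel[1, 64:126, ], steps[[2]]$accel, tolerance = 0)
  expect_error(assemble_samples(steps, k = 0), "k must be")
})

test_that("standardization fits on train only and maps zero variance to 0", {
  samples <- small_dataset()
  idx <- split_random_subsample(n_samples(samples), 100, 50, 1, seed = 5)[[1]]
  train <- subset_samples(samples, idx$train)
  test <- subset_samples(samples, idx$test)
  std <- standardize_samples(train, test)

  m <- std$train$accel; dim(m) <- c(dim(m)[1], prod(dim(m)[2:3]))
  raw <- train$accel; dim(raw) <- dim(m)
  sds <- apply(raw, 2, sd)
  expect_lt(max(abs(colMeans(m))), 1e-9)
  v <- apply(m, 2, var)
  expect_equal(unname(v[sds > 1e-12]), rep(1, sum(sds > 1e-12)), tolerance = 1e-9)
  expect_true(all(abs(m[, sds <= 1e-12]) == 0))

  # leakage check: a shifted copy of train keeps a non-zero mean under the
  # train-fitted transform
  shifted <- train
  shifted$accel <- shifted$accel + 2
  std2 <- standardize_samples(train, shifted)
  m2 <- std2$test$accel; dim(m2) <- dim(m)
  expect_gt(min(abs(colMeans(m2)[sds > 1e-12])), 0.1)

  # degenerate single-sample train: every feature has zero variance
  one <- subset_samples(samples, 1)
  std3 <- standardize_samples(one)
  expect_true(all(std3$train$pressure == 0) && all(std3$train$accel == 0))

  expect_error(standardize_samples(subset_samples(samples, integer(0))),
               "non-empty")
})
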