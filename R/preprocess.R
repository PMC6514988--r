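# Unit-step preprocessing: phase-boundary detection on the left-foot pressure
# array, swing-phase noise removal, segmentation into unit steps, length
# normalization, lexicographic flattening and k-step sample assembly.
#
# Frame indices are 1-based; all intervals are half-open [start, end).

#' Detect swing/stance phase boundaries from the pressure array
#'
#' Scans the 8 left-foot pressure channels. A swing start is the first frame
#' of each maximal run where the left-foot channel sum reaches 0 after being
#' non-zero (or frame 1 itself); the paired stance start is the first
#' subsequent frame on which two or more left-foot channels are non-zero.
#' A trailing swing start with no paired stance start is retained in
#' `swing_starts` (it delimits the last unit step) but yields no pair.
#'
#' @param pressure frames x 16 integer matrix, values in \{0,1,2\}.
#' @return an object of class `gait_phase_annotation` with integer vectors
#'   `swing_starts` and `stance_starts` (`length(swing_starts)` equals
#'   `length(stance_starts)` or exceeds it by one), and `n_frames`.
#' @export
#' @examples
#' p <- matrix(0L, 8, 16)
#' p[1:2, 1:2] <- 1L; p[7:8, 1:2] <- 1L   # stance, swing (frames 3-6), stance
#' detect_phase_boundaries(p)
detect_phase_boundaries <- function(pressure) {
  pressure <- as.matrix(pressure)
  abort_if(ncol(pressure) != N_PRESSURE, "pressure must have %d columns", N_PRESSURE)
  abort_if(nrow(pressure) < 1, "pressure must have at least one frame")
  left <- pressure[, LEFT_PRESSURE, drop = FALSE]
  sums <- rowSums(left)
  nact <- rowSums(left != 0)
  swing <- integer(); stance <- integer()
  seeking <- "swing"
  for (i in seq_along(sums)) {
    if (seeking == "swing") {
      if (sums[i] == 0) {
        swing <- c(swing, i)
        seeking <- "stance"
      }
    } else {
      if (nact[i] >= 2) {
        stance <- c(stance, i)
        seeking <- "swing"
      }
    }
  }
  structure(list(swing_starts = swing, stance_starts = stance,
                 foot = "left", n_frames = nrow(pressure)),
            class = "gait_phase_annotation")
}

#' @export
print.gait_phase_annotation <- function(x, ...) {
  cat(sprintf("<gait_phase_annotation> %d swing start(s), %d stance start(s) over %d frames\n",
              length(x$swing_starts), length(x$stance_starts), x$n_frames))
  invisible(x)
}

#' Remove single-sensor swing-phase noise from the pressure array
#'
#' Inside every detected swing interval `[swing_start, stance_start)` (the
#' trailing unpaired swing extends to the end of the recording), any frame
#' whose left-foot channel sum is exactly 1 is declared noise and the single
#' offending channel is set to 0 — the hardware artifact in which one sensor
#' reads 1 while the foot is airborne. In addition, a maximal contiguous run
#' of sum-1 frames immediately preceding a detected swing start is zeroed:
#' such frames are the same artifact landing on the true start of the swing,
#' where it masks the zero-sum onset from the detector. A frame with a sum of
#' 2 or more (e.g. one sensor at level 2) is never touched.
#'
#' @param pressure frames x 16 pressure matrix.
#' @param annotation a `gait_phase_annotation` produced from `pressure` (or
#'   from the noise-free truth of the same recording).
#' @return list with `pressure` (cleaned matrix) and `corrections` (number of
#'   frames altered).
#' @seealso [detect_phase_boundaries()], [segment_unit_steps()]
#' @export
reduce_swing_noise <- function(pressure, annotation) {
  pressure <- as.matrix(pressure)
  left <- pressure[, LEFT_PRESSURE, drop = FALSE]
  sums <- rowSums(left)
  nfr <- nrow(pressure)
  sw <- annotation$swing_starts
  st <- annotation$stance_starts
  fix <- integer()
  for (j in seq_along(sw)) {
    end <- if (j <= length(st)) st[j] else nfr + 1L
    if (end > sw[j]) {
      idx <- sw[j]:(end - 1L)
      fix <- c(fix, idx[sums[idx] == 1])
    }
    # artifact covering the true swing onset: sum-1 run just before sw[j]
    i <- sw[j] - 1L
    while (i >= 1L && sums[i] == 1) {
      fix <- c(fix, i)
      i <- i - 1L
    }
  }
  fix <- unique(fix)
  if (length(fix) > 0) {
    ch <- max.col(left[fix, , drop = FALSE] != 0, ties.method = "first")
    pressure[cbind(fix, ch)] <- 0L
  }
  list(pressure = pressure, corrections = length(fix))
}

#' Segment a recording into unit steps
#'
#' A unit step runs from a left-foot swing start to the end of the following
#' stance phase, operationalized as the next swing start so that steps tile
#' the recording without gaps. The pressure array is cleaned with
#' [reduce_swing_noise()] (boundaries re-detected afterwards) before slicing;
#' all three modality arrays are sliced with identical frame intervals.
#' Frames before the first swing start are discarded, and a final step whose
#' stance runs into the end of the recording (truncated mid-stance) is
#' dropped.
#'
#' @param recording a valid `gait_recording`.
#' @return list of `gait_step` objects, each with fields `pressure`
#'   (L x 16), `accel` (L x 6), `gyro` (L x 6), `L`, `label`, `start`, `end`
#'   (half-open frame interval in the recording). May be empty.
#' @export
segment_unit_steps <- function(recording) {
  viol <- validate_recording(recording)
  abort_if(length(viol) > 0, "invalid recording: %s", paste(viol, collapse = "; "))
  if (n_frames(recording) == 0) return(list())
  ann <- detect_phase_boundaries(recording$pressure)
  cleaned <- reduce_swing_noise(recording$pressure, ann)$pressure
  ann <- detect_phase_boundaries(cleaned)
  sw <- ann$swing_starts
  n_pairs <- length(ann$stance_starts)
  if (n_pairs == 0) return(list())
  # step i spans [sw[i], sw[i+1]); the last pair needs a trailing swing start
  # to certify its stance completed before the recording ended
  n_steps <- if (length(sw) > n_pairs) n_pairs else n_pairs - 1L
  if (n_steps < 1) return(list())
  lapply(seq_len(n_steps), function(i) {
    a <- sw[i]; b <- sw[i + 1L]
    idx <- a:(b - 1L)
    structure(list(pressure = cleaned[idx, , drop = FALSE],
                   accel = recording$accel[idx, , drop = FALSE],
                   gyro = recording$gyro[idx, , drop = FALSE],
                   L = length(idx), label = recording$label,
                   start = a, end = b),
              class = "gait_step")
  })
}

#' @export
print.gait_step <- function(x, ...) {
  cat(sprintf("<gait_step> %d frames [%d, %d), label=%s%s\n", x$L, x$start, x$end,
              x$label, if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Resample a unit step to a fixed length
#'
#' Each channel is independently linearly interpolated on a uniform grid over
#' `[0, L-1]` evaluated at `t` equally spaced points. Pressure channels are
#' rounded to the nearest integer (R's round-half-to-even) and clipped back
#' into \{0,1,2\}; accel/gyro channels stay continuous. The default target
#' length 63 is the shortest unit step observed in the reference experiment.
#'
#' @param step a `gait_step` with `L >= 2`.
#' @param t target length in frames (default 63).
#' @return a normalized `gait_step` with `L == t` and `normalized = TRUE`.
#' @export
normalize_step <- function(step, t = 63L) {
  abort_if(t < 1, "target length t must be >= 1")
  abort_if(step$L < 2, "degenerate unit step: need at least 2 frames, got %d", step$L)
  resample <- function(mat) {
    x <- seq(0, step$L - 1)
    xout <- seq(0, step$L - 1, length.out = t)
    apply(mat, 2, function(col) stats::approx(x, col, xout = xout)$y)
  }
  pr <- resample(step$pressure)
  pr <- pmin(pmax(round(pr), 0), 2)
  storage.mode(pr) <- "integer"
  structure(list(pressure = pr,
                 accel = resample(step$accel),
                 gyro = resample(step$gyro),
                 L = as.integer(t), label = step$label,
                 start = step$start, end = step$end, normalized = TRUE),
            class = "gait_step")
}

#' Flatten a normalized step into per-modality vectors
#'
#' Lexicographic (time-major) unrolling: the values of frame 1 across all
#' channels come first, then frame 2, and so on. For `t = 63` the vectors
#' have lengths 1008 (pressure), 378 (accel) and 378 (gyro). The operation is
#' invertible given `(t, W)`; see [unflatten_step_vector()].
#'
#' @param step a normalized `gait_step`.
#' @return list with numeric vectors `pressure_vec`, `accel_vec`, `gyro_vec`.
#' @export
flatten_step <- function(step) {
  abort_if(!isTRUE(step$normalized), "flatten_step expects a normalized step")
  list(pressure_vec = as.vector(t(step$pressure)),
       accel_vec = as.vector(t(step$accel)),
       gyro_vec = as.vector(t(step$gyro)))
}

#' Invert the lexicographic flattening
#'
#' @param vec flattened vector of length `t * W`.
#' @param W number of channels.
#' @return a `t x W` matrix.
#' @export
unflatten_step_vector <- function(vec, W) {
  abort_if(length(vec) %% W != 0, "vector length %d is not a multiple of W=%d",
           length(vec), W)
  matrix(vec, ncol = W, byrow = TRUE)
}

#' Assemble consecutive normalized steps into k-step classifier samples
#'
#' Groups consecutive, non-overlapping windows of `k` steps (chronological
#' within the recording they came from) and stacks each window row-wise into
#' a `(t*k) x W` array per modality. Leftover steps (fewer than `k`) are
#' discarded.
#'
#' @param steps list of normalized `gait_step`s sharing the same `t` and label
#'   (one recording's steps, in order).
#' @param k steps per sample (>= 1).
#' @param source optional provenance string recorded in the manifest.
#' @return a `gait_samples` object; see [gait_samples()].
#' @export
assemble_samples <- function(steps, k = 1L, source = NA_character_) {
  abort_if(k < 1, "k must be >= 1")
  if (length(steps) == 0) return(empty_gait_samples(t = 0L, k = as.integer(k)))
  abort_if(!all(vapply(steps, function(s) isTRUE(s$normalized), logical(1))),
           "assemble_samples expects normalized steps")
  t_len <- unique(vapply(steps, function(s) s$L, integer(1)))
  abort_if(length(t_len) != 1, "steps must share the same normalized length t")
  n_samp <- length(steps) %/% k
  if (n_samp == 0) return(empty_gait_samples(t = t_len, k = as.integer(k)))
  build <- function(field, W) {
    arr <- array(0, dim = c(n_samp, t_len * k, W))
    for (i in seq_len(n_samp)) {
      block <- do.call(rbind, lapply(steps[(i - 1L) * k + seq_len(k)],
                                     function(s) s[[field]]))
      arr[i, , ] <- block
    }
    arr
  }
  labels <- gait_label_code(vapply(steps[seq_len(n_samp) * k], function(s) s$label,
                                   character(1)))
  gait_samples(pressure = build("pressure", N_PRESSURE),
               accel = build("accel", N_ACCEL),
               gyro = build("gyro", N_GYRO),
               label = labels, t = t_len, k = as.integer(k),
               manifest = data.frame(sample = seq_len(n_samp),
                                     source = rep(source, n_samp),
                                     label = gait_label_name(labels),
                                     stringsAsFactors = FALSE))
}

#' Container for assembled gait samples
#'
#' Holds one `(n, t*k, W)` array per modality plus 0-based class codes and a
#' provenance manifest. Modalities are named entries so derived channel
#' groups (e.g. per-foot splits from [split_feet()]) can ride along.
#'
#' @param pressure n x (t*k) x 16 array.
#' @param accel n x (t*k) x 6 array.
#' @param gyro n x (t*k) x 6 array.
#' @param label integer class codes (0..6), length n.
#' @param t normalized step length.
#' @param k steps per sample.
#' @param manifest data frame of per-sample provenance (optional).
#' @return an object of class `gait_samples`.
#' @export
gait_samples <- function(pressure, accel, gyro, label, t, k, manifest = NULL) {
  n <- length(label)
  for (nm in c("pressure", "accel", "gyro")) {
    arr <- get(nm)
    abort_if(length(dim(arr)) != 3 || dim(arr)[1] != n,
             "%s must be an (n, t*k, W) array with n = length(label)", nm)
    abort_if(dim(arr)[2] != t * k, "%s has %d rows per sample; expected t*k = %d",
             nm, dim(arr)[2], t * k)
  }
  if (is.null(manifest))
    manifest <- data.frame(sample = seq_len(n), source = NA_character_,
                           label = if (n > 0) gait_label_name(label) else character(0),
                           stringsAsFactors = FALSE)
  structure(list(pressure = pressure, accel = accel, gyro = gyro,
                 label = as.integer(label), t = as.integer(t), k = as.integer(k),
                 manifest = manifest),
            class = "gait_samples")
}

empty_gait_samples <- function(t, k) {
  gait_samples(pressure = array(0, c(0, t * k, N_PRESSURE)),
               accel = array(0, c(0, t * k, N_ACCEL)),
               gyro = array(0, c(0, t * k, N_GYRO)),
               label = integer(0), t = t, k = k,
               manifest = data.frame(sample = integer(0), source = character(0),
                                     label = character(0), stringsAsFactors = FALSE))
}

#' @export
print.gait_samples <- function(x, ...) {
  cat(sprintf("<gait_samples> %d samples (t=%d, k=%d); modalities: %s\n",
              length(x$label), x$t, x$k,
              paste(setdiff(names(x), c("label", "t", "k", "manifest")), collapse = ", ")))
  if (length(x$label) > 0) print(table(gait_label_name(x$label)))
  invisible(x)
}

#' Number of samples in a `gait_samples` container
#' @param samples a `gait_samples` object.
#' @return integer count.
#' @export
n_samples <- function(samples) length(samples$label)

#' Subset a `gait_samples` container by sample index
#' @param samples a `gait_samples` object.
#' @param idx integer index vector.
#' @return a `gait_samples` with the selected samples.
#' @export
subset_samples <- function(samples, idx) {
  out <- samples
  for (nm in modality_names(samples)) out[[nm]] <- samples[[nm]][idx, , , drop = FALSE]
  out$label <- samples$label[idx]
  out$manifest <- samples$manifest[idx, , drop = FALSE]
  out
}

#' Concatenate several `gait_samples` containers
#' @param ... `gait_samples` objects sharing `t`, `k` and modalities.
#' @return a combined `gait_samples`.
#' @export
combine_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "gait_samples"))
    parts <- parts[[1]]
  parts <- Filter(function(p) n_samples(p) > 0, parts)
  abort_if(length(parts) == 0, "no non-empty sample sets to combine")
  t0 <- parts[[1]]$t; k0 <- parts[[1]]$k
  abort_if(!all(vapply(parts, function(p) p$t == t0 && p$k == k0, logical(1))),
           "all sample sets must share t and k")
  out <- parts[[1]]
  for (nm in modality_names(out)) {
    mats <- lapply(parts, function(p) p[[nm]])
    arr <- array(0, dim = c(sum(vapply(mats, function(m) dim(m)[1], numeric(1))),
                            dim(mats[[1]])[2], dim(mats[[1]])[3]))
    at <- 1L
    for (m in mats) {
      if (dim(m)[1] > 0) arr[at:(at + dim(m)[1] - 1L), , ] <- m
      at <- at + dim(m)[1]
    }
    out[[nm]] <- arr
  }
  out$label <- unlist(lapply(parts, function(p) p$label))
  out$manifest <- do.call(rbind, lapply(parts, function(p) p$manifest))
  out$manifest$sample <- seq_len(nrow(out$manifest))
  out
}

modality_names <- function(samples) {
  setdiff(names(samples), c("label", "t", "k", "manifest"))
}

#' Split accel/gyro channels into per-foot 3-wide modalities
#'
#' The stored acceleration and gyro arrays carry both feet (6 columns:
#' left x,y,z then right x,y,z). Some analyses treat each foot's 3-axis
#' array as its own modality of width 3; this helper adds `accel_left`,
#' `accel_right`, `gyro_left`, `gyro_right` entries to the container.
#'
#' @param samples a `gait_samples` object.
#' @return the container with four additional 3-wide modalities.
#' @export
split_feet <- function(samples) {
  for (nm in c("accel", "gyro")) {
    samples[[paste0(nm, "_left")]] <- samples[[nm]][, , 1:3, drop = FALSE]
    samples[[paste0(nm, "_right")]] <- samples[[nm]][, , 4:6, drop = FALSE]
  }
  samples
}

#' Run the full preprocessing pipeline over recordings
#'
#' Segments each recording ([segment_unit_steps()], which cleans swing-phase
#' noise), normalizes every step to `t` frames, assembles non-overlapping
#' `k`-step samples per recording, and concatenates the results.
#'
#' @param recordings list of `gait_recording`s.
#' @param k steps per sample.
#' @param t normalized step length (default 63). Use `t = NULL` to recompute
#'   it as the shortest observed unit step.
#' @return a `gait_samples` object.
#' @export
preprocess_recordings <- function(recordings, k = 1L, t = 63L) {
  steps_per_rec <- lapply(recordings, segment_unit_steps)
  if (is.null(t)) {
    lens <- unlist(lapply(steps_per_rec, function(st) vapply(st, function(s) s$L, integer(1))))
    abort_if(length(lens) == 0, "no complete unit steps found in any recording")
    t <- min(lens)
  }
  per_rec <- lapply(seq_along(recordings), function(i) {
    steps <- lapply(steps_per_rec[[i]], normalize_step, t = t)
    src <- recordings[[i]]$subject_id
    assemble_samples(steps, k = k, source = sprintf("recording_%03d[%s]", i, src))
  })
  combine_samples(per_rec)
}

#' Standardize samples with training-set statistics
#'
#' Fits a per-feature (per time/channel cell, per modality) affine transform
#' on the training set only — zero mean, unit variance, with zero-variance
#' features mapped to 0 — and applies the same transform to the test set, so
#' no test information leaks into the scaling.
#'
#' @param train a non-empty `gait_samples`.
#' @param test an optional `gait_samples` with the same shape.
#' @return list with `train`, `test` (NULL if not supplied) and `stats`
#'   (per-modality `center`/`scale` vectors).
#' @export
standardize_samples <- function(train, test = NULL) {
  abort_if(n_samples(train) == 0, "training set must be non-empty")
  stats <- list()
  for (nm in modality_names(train)) {
    arr <- train[[nm]]
    d <- dim(arr)
    m <- arr; dim(m) <- c(d[1], d[2] * d[3])
    center <- colMeans(m)
    v <- colMeans(m * m) - center^2
    v <- v * d[1] / max(1, d[1] - 1)        # unbiased variance
    scale <- sqrt(pmax(v, 0))
    scale[scale < 1e-12] <- Inf             # zero-variance feature -> 0
    stats[[nm]] <- list(center = center, scale = scale)
    m <- sweep(sweep(m, 2, center), 2, scale, "/")
    dim(m) <- d
    train[[nm]] <- m
  }
  if (!is.null(test)) {
    for (nm in modality_names(test)) {
      arr <- test[[nm]]
      d <- dim(arr)
      m <- arr; dim(m) <- c(d[1], d[2] * d[3])
      m <- sweep(sweep(m, 2, stats[[nm]]$center), 2, stats[[nm]]$scale, "/")
      dim(m) <- d
      test[[nm]] <- m
    }
  }
  list(train = train, test = test, stats = stats)
}
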