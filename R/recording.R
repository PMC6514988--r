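# Domain types: gait labels and sensor recordings.

#' The seven gait type labels
#'
#' Returns the fixed label ordering used throughout the package. Integer class
#' codes 0--6 follow this order.
#'
#' @return character vector of length 7.
#' @export
#' @examples
#' gait_types()
gait_types <- function() {
  c("walking", "fast_walking", "running", "stair_climbing",
    "stair_descending", "hill_climbing", "hill_descending")
}

#' Convert gait labels to integer codes and back
#'
#' Codes are 0-based (0 = walking ... 6 = hill_descending) and the mapping is
#' bijective.
#'
#' @param label character vector of gait type names.
#' @param code integer vector of codes in 0..6.
#' @return `gait_label_code()` returns integer codes; `gait_label_name()`
#'   returns label names.
#' @export
gait_label_code <- function(label) {
  code <- match(label, gait_types()) - 1L
  abort_if(anyNA(code), "unknown gait label(s): %s",
           paste(unique(label[is.na(code)]), collapse = ", "))
  code
}

#' @rdname gait_label_code
#' @export
gait_label_name <- function(code) {
  abort_if(any(code < 0L | code > 6L | code != as.integer(code)),
           "gait label codes must be integers in 0..6")
  gait_types()[code + 1L]
}

#' Construct a smart-insole sensor recording
#'
#' Bundles the three synchronized sensor arrays of one recording session:
#' 16 quantized pressure channels (8 per foot, values 0/1/2), 6 acceleration
#' channels and 6 gyro channels (left x,y,z then right x,y,z), all sampled on
#' a common clock (100 Hz by default).
#'
#' @param pressure frames x 16 integer matrix with values in \{0,1,2\};
#'   columns 1--8 are the left foot, 9--16 the right foot.
#' @param accel frames x 6 numeric matrix.
#' @param gyro frames x 6 numeric matrix.
#' @param label gait type, one of [gait_types()].
#' @param subject_id free-form subject identifier.
#' @param sample_rate_hz sampling rate, positive.
#' @return an object of class `gait_recording`.
#' @export
gait_recording <- function(pressure, accel, gyro, label,
                           subject_id = "anonymous", sample_rate_hz = 100) {
  rec <- structure(
    list(pressure = as.matrix(pressure), accel = as.matrix(accel),
         gyro = as.matrix(gyro), label = as.character(label),
         subject_id = as.character(subject_id),
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "gait_recording")
  storage.mode(rec$pressure) <- "integer"
  storage.mode(rec$accel) <- "double"
  storage.mode(rec$gyro) <- "double"
  viol <- validate_recording(rec)
  abort_if(length(viol) > 0, "invalid recording: %s", paste(viol, collapse = "; "))
  rec
}

#' Validate a sensor recording
#'
#' Pure check of all recording invariants: matching frame counts across the
#' three arrays, fixed channel counts (16/6/6), pressure values in \{0,1,2\},
#' a known gait label, and a positive sampling rate. Violations are reported,
#' not raised.
#'
#' @param recording a `gait_recording` (or a bare list with the same fields).
#' @return character vector of violation descriptions; empty iff valid.
#' @export
validate_recording <- function(recording) {
  v <- character()
  p <- recording$pressure; a <- recording$accel; g <- recording$gyro
  if (!is.matrix(p) || ncol(p) != N_PRESSURE)
    v <- c(v, sprintf("pressure must be a matrix with %d columns", N_PRESSURE))
  if (!is.matrix(a) || ncol(a) != N_ACCEL)
    v <- c(v, sprintf("accel must be a matrix with %d columns", N_ACCEL))
  if (!is.matrix(g) || ncol(g) != N_GYRO)
    v <- c(v, sprintf("gyro must be a matrix with %d columns", N_GYRO))
  if (is.matrix(p) && is.matrix(a) && is.matrix(g)) {
    n <- c(pressure = nrow(p), accel = nrow(a), gyro = nrow(g))
    if (length(unique(n)) != 1L)
      v <- c(v, sprintf("frame counts differ across arrays (pressure=%d, accel=%d, gyro=%d)",
                        n[1], n[2], n[3]))
  }
  if (is.matrix(p) && nrow(p) > 0) {
    bad <- which(!(p %in% c(0L, 1L, 2L)))
    if (length(bad) > 0) {
      fr <- ((bad[1] - 1L) %% nrow(p)) + 1L
      ch <- ((bad[1] - 1L) %/% nrow(p)) + 1L
      v <- c(v, sprintf("pressure value %s outside {0,1,2} at frame %d, channel %d (%d offending value(s))",
                        format(p[bad[1]]), fr, ch, length(bad)))
    }
  }
  if (!recording$label %in% gait_types())
    v <- c(v, sprintf("unknown gait label '%s'", recording$label))
  if (!is.numeric(recording$sample_rate_hz) || length(recording$sample_rate_hz) != 1 ||
      !is.finite(recording$sample_rate_hz) || recording$sample_rate_hz <= 0)
    v <- c(v, "sample_rate_hz must be a single positive number")
  v
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d frames @ %g Hz, label=%s, subject=%s\n",
              nrow(x$pressure), x$sample_rate_hz, x$label, x$subject_id))
  invisible(x)
}

#' Number of frames in a recording
#' @param recording a `gait_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(recording) nrow(recording$pressure)
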