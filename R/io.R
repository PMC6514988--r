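# On-disk format for recordings: one UTF-8 comma-delimited file per recording.
# '#'-prefixed "key: value" header lines (subject_id, label, sample_rate_hz)
# followed by one row per frame with 28 columns in fixed order:
# 16 pressure (left 1-8, right 1-8), 6 accel (left xyz, right xyz), 6 gyro.

#' Write a recording to a delimited text file
#'
#' Integers round-trip losslessly; accel/gyro values are printed with 17
#' significant digits so `read_recording()` reproduces them bit-for-bit.
#' A 0-frame recording produces a header-only file.
#'
#' @param recording a valid `gait_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path) {
  viol <- validate_recording(recording)
  abort_if(length(viol) > 0, "refusing to write invalid recording: %s",
           paste(viol, collapse = "; "))
  header <- c(
    sprintf("# subject_id: %s", recording$subject_id),
    sprintf("# label: %s", recording$label),
    sprintf("# sample_rate_hz: %s", format(recording$sample_rate_hz, digits = 17))
  )
  lines <- header
  if (nrow(recording$pressure) > 0) {
    fmt_cols <- function(m, ...) {
      out <- apply(m, 2, format, ...)
      if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
      out
    }
    body <- cbind(
      fmt_cols(recording$pressure, scientific = FALSE, trim = TRUE),
      fmt_cols(recording$accel, digits = 17, scientific = TRUE, trim = TRUE),
      fmt_cols(recording$gyro, digits = 17, scientific = TRUE, trim = TRUE)
    )
    lines <- c(lines, apply(body, 1, paste, collapse = ","))
  }
  con <- tryCatch(suppressWarnings(file(path, "w", encoding = "UTF-8")),
                  error = function(e) stop(sprintf("cannot open '%s' for writing: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' Parses the dialect written by [write_recording()]. Malformed rows raise a
#' parse error naming the file line number; pressure values outside \{0,1,2\}
#' raise a validation error naming the line.
#'
#' @param path file path.
#' @return a `gait_recording`.
#' @export
read_recording <- function(path) {
  abort_if(!file.exists(path), "recording file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- startsWith(lines, "#")
  meta <- list(subject_id = "anonymous", label = NA_character_, sample_rate_hz = 100)
  for (h in lines[is_header]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  abort_if(is.na(meta$label), "file %s has no '# label:' header line", path)
  data_idx <- which(!is_header & nzchar(trimws(lines)))
  nfr <- length(data_idx)
  pressure <- matrix(0L, nfr, N_PRESSURE)
  accel <- matrix(0, nfr, N_ACCEL)
  gyro <- matrix(0, nfr, N_GYRO)
  if (nfr > 0) {
    fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != N_COLUMNS)
    abort_if(length(bad) > 0,
             "parse error at line %d of %s: expected %d comma-separated fields, found %d",
             data_idx[bad[1]], path, N_COLUMNS, nf[bad[1]])
    vals <- suppressWarnings(as.numeric(unlist(fields)))
    if (anyNA(vals)) {
      row <- (which(is.na(vals))[1] - 1L) %/% N_COLUMNS + 1L
      stop(sprintf("parse error at line %d of %s: non-numeric field", data_idx[row], path),
           call. = FALSE)
    }
    m <- matrix(vals, nrow = nfr, ncol = N_COLUMNS, byrow = TRUE)
    pvals <- m[, 1:N_PRESSURE, drop = FALSE]
    badp <- which(!(pvals %in% c(0, 1, 2)))
    if (length(badp) > 0) {
      row <- ((badp[1] - 1L) %% nfr) + 1L
      ch <- ((badp[1] - 1L) %/% nfr) + 1L
      stop(sprintf("validation error at line %d of %s: pressure value %s (channel %d) outside {0,1,2}",
                   data_idx[row], path, format(pvals[badp[1]]), ch), call. = FALSE)
    }
    pressure <- pvals
    storage.mode(pressure) <- "integer"
    accel <- m[, N_PRESSURE + seq_len(N_ACCEL), drop = FALSE]
    gyro <- m[, N_PRESSURE + N_ACCEL + seq_len(N_GYRO), drop = FALSE]
  }
  gait_recording(pressure, accel, gyro, label = meta$label,
                 subject_id = meta$subject_id,
                 sample_rate_hz = as.numeric(meta$sample_rate_hz))
}
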