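# Container file for assembled gait samples: same comma-delimited dialect as
# recordings, one '#'-headed block of t*k frames per sample.

#' Write assembled samples to a container file
#'
#' Header lines record `t`, `k` and the sample count; each sample follows as
#' a `# sample:` line (index, label, source) and `t*k` rows of the 28
#' recording columns. Only the three base modalities are stored.
#'
#' @param samples a `gait_samples` (raw, pre-standardization).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  n <- n_samples(samples)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# t: %d", samples$t),
               sprintf("# k: %d", samples$k),
               sprintf("# n: %d", n)), con)
  for (i in seq_len(n)) {
    src <- samples$manifest$source[i]
    writeLines(sprintf("# sample: %d, label: %s, source: %s",
                       i, gait_label_name(samples$label[i]),
                       if (is.na(src)) "NA" else src), con)
    block <- cbind(format(samples$pressure[i, , ], scientific = FALSE, trim = TRUE),
                   format(samples$accel[i, , ], digits = 17, trim = TRUE),
                   format(samples$gyro[i, , ], digits = 17, trim = TRUE))
    writeLines(apply(block, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a sample container file
#'
#' @param path file written by [write_samples()].
#' @return a `gait_samples`.
#' @export
read_samples <- function(path) {
  abort_if(!file.exists(path), "sample container does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)[1]
    abort_if(is.na(m), "container %s lacks '# %s:' header", path, key)
    as.integer(sub(sprintf("^#\\s*%s:\\s*", key), "", m))
  }
  t_len <- get_meta("t"); k <- get_meta("k"); n <- get_meta("n")
  rows <- t_len * k
  sample_hdr <- grep("^#\\s*sample:", lines)
  abort_if(length(sample_hdr) != n,
           "container %s declares %d samples but has %d sample blocks",
           path, n, length(sample_hdr))
  pressure <- array(0, c(n, rows, N_PRESSURE))
  accel <- array(0, c(n, rows, N_ACCEL))
  gyro <- array(0, c(n, rows, N_GYRO))
  labels <- integer(n); sources <- character(n)
  for (i in seq_len(n)) {
    hdr <- lines[sample_hdr[i]]
    m <- regmatches(hdr, regexec("label:\\s*([a-z_]+),\\s*source:\\s*(.*)$", hdr))[[1]]
    labels[i] <- gait_label_code(m[2])
    sources[i] <- m[3]
    block <- lines[sample_hdr[i] + seq_len(rows)]
    vals <- as.numeric(unlist(strsplit(block, ",", fixed = TRUE)))
    abort_if(length(vals) != rows * N_COLUMNS,
             "sample %d in %s has the wrong shape", i, path)
    mat <- matrix(vals, nrow = rows, byrow = TRUE)
    pressure[i, , ] <- mat[, 1:N_PRESSURE]
    accel[i, , ] <- mat[, N_PRESSURE + seq_len(N_ACCEL)]
    gyro[i, , ] <- mat[, N_PRESSURE + N_ACCEL + seq_len(N_GYRO)]
  }
  gait_samples(pressure, accel, gyro, label = labels, t = t_len, k = k,
               manifest = data.frame(sample = seq_len(n), source = sources,
                                     label = gait_label_name(labels),
                                     stringsAsFactors = FALSE))
}
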