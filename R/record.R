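#' Acceleration recordings
#'
#' An `accel_record` holds a uniformly sampled hand-acceleration signal from a
#' pen-held biaxial accelerometer, in m/s^2, together with its sampling rate
#' and the labels identifying the recording: subject, condition (`"rest"` with
#' hands on the lap, `"postural"` with arms extended at shoulder level) and
#' side (`"R"`/`"L"`). One or two axes are accepted; two-axis recordings are
#' stored as a two-column matrix.
#'
#' @param samples numeric vector (one axis) or matrix with one column per axis,
#'   accelerations in m/s^2.
#' @param sampling_rate sampling frequency in Hz.
#' @param subject_id subject label.
#' @param condition `"rest"` or `"postural"`.
#' @param side `"R"` or `"L"`.
#' @return An object of class `accel_record`.
#' @examples
#' t <- seq(0, 16, by = 1 / 128)[-1]
#' rec <- accel_record(sin(2 * pi * 7 * t), 128)
#' rec
#' @export
accel_record <- function(samples, sampling_rate, subject_id = "S1",
                         condition = "rest", side = "R") {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) > 2L)
    stop_tremor("at most two acceleration axes are supported, got ", ncol(samples))
  if (any(!is.finite(samples)))
    stop_tremor("acceleration samples must all be finite")
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop_tremor("'sampling_rate' must be positive")
  if (nrow(samples) / sampling_rate < 8)
    stop_tremor("recording must cover at least 8 s of data; got ",
                signif(nrow(samples) / sampling_rate, 3), " s")
  condition <- match.arg(condition, CONDITIONS)
  side <- match.arg(side, SIDES)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         subject_id = as.character(subject_id),
         condition = condition, side = side),
    class = "accel_record")
}

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf("<accel_record> subject %s, %s tremor, side %s\n",
              x$subject_id, x$condition, x$side))
  cat(sprintf("  %d samples x %d axis(es) @ %g Hz (%.1f s), RMS %.3f m/s^2\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
plot.accel_record <- function(x, max_sec = 4, ...) {
  n <- min(nrow(x$samples), ceiling(max_sec * x$sampling_rate))
  t <- seq_len(n) / x$sampling_rate
  plot(t, x$samples[seq_len(n), 1], type = "l", xlab = "time (s)",
       ylab = "acceleration (m/s^2)",
       main = sprintf("%s %s %s", x$subject_id, x$condition, x$side), ...)
  if (ncol(x$samples) == 2L)
    lines(t, x$samples[seq_len(n), 2], col = "grey50")
  invisible(x)
}

#' Write an acceleration recording to a delimited text file
#'
#' Plain-text signal format: comment header lines
#' `# sampling_rate_hz=...` and `# subject=... condition=... side=...`,
#' then tab-separated columns `t`, `ax` (and `ay` for biaxial recordings),
#' in seconds and m/s^2.
#'
#' @param record an [accel_record].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_record <- function(record, path) {
  stopifnot(inherits(record, "accel_record"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_tremor("cannot write '", path, "': ",
                                                  conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", record$sampling_rate),
               sprintf("# subject=%s condition=%s side=%s",
                       record$subject_id, record$condition, record$side)), con)
  n <- nrow(record$samples)
  df <- data.frame(t = seq_len(n) / record$sampling_rate,
                   ax = record$samples[, 1])
  if (ncol(record$samples) == 2L) df$ay <- record$samples[, 2]
  write.table(format(df, digits = 9, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an acceleration recording written by [write_accel_record()]
#'
#' @param path file path.
#' @return An [accel_record].
#' @export
read_accel_record <- function(path) {
  if (!file.exists(path)) stop_tremor("signal file not found: ", path)
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("sampling_rate_hz=", hdr, value = TRUE)
  if (!length(fs_line))
    stop_tremor("malformed signal file (no sampling_rate_hz header): ", path)
  fs <- as.numeric(sub(".*sampling_rate_hz=([0-9.eE+-]+).*", "\\1", fs_line[1]))
  meta <- c(subject = "S1", condition = "rest", side = "R")
  lab_line <- grep("subject=", hdr, value = TRUE)
  if (length(lab_line)) {
    for (key in names(meta)) {
      m <- regmatches(lab_line[1],
                      regexec(paste0(key, "=([^ ]+)"), lab_line[1]))[[1]]
      if (length(m) == 2L) meta[[key]] <- m[2]
    }
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!("ax" %in% names(df)) || nrow(df) == 0L)
    stop_tremor("malformed signal file (no sample columns): ", path)
  samples <- if ("ay" %in% names(df)) cbind(df$ax, df$ay) else df$ax
  accel_record(samples, fs, subject_id = meta[["subject"]],
               condition = meta[["condition"]], side = meta[["side"]])
}
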