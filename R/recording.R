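#' Epoched multichannel EEG recording
#'
#' The common carrier for resting and chirp data: a channels x epochs x time
#' array of microvolt samples plus sampling rate, channel labels, montage
#' identity and task tag. For chirp recordings each "epoch" is one stimulus
#' trial and `time0` places the first sample relative to stimulus onset
#' (e.g. -0.5 for a 500 ms pre-stimulus window); for resting data epochs are
#' consecutive segments and `time0` is 0.
#'
#' @param samples numeric array `[channel, epoch, time]` in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels (length = dim 1).
#' @param montage montage identifier string.
#' @param task `"rest"` or `"chirp"`.
#' @param time0 time (s) of the first sample relative to stimulus onset.
#' @return an object of class `epoched_recording`.
#' @export
epoched_recording <- function(samples, fs, labels,
                              montage = "custom", task = c("rest", "chirp"),
                              time0 = 0) {
  task <- match.arg(task)
  stopifnot(is.array(samples), length(dim(samples)) == 3, fs > 0)
  if (length(labels) != dim(samples)[1])
    stop_fx("%d labels for %d channels", length(labels), dim(samples)[1])
  if (anyDuplicated(labels)) stop_fx("channel labels must be unique")
  structure(
    list(samples = samples, fs = fs, labels = labels,
         montage = montage, task = task, time0 = time0),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<epoched_recording> %s task, montage %s\n", x$task, x$montage))
  cat(sprintf("  %d channels x %d epochs x %d samples @ %g Hz (%.3g s/epoch)\n",
              d[1], d[2], d[3], x$fs, d[3] / x$fs))
  invisible(x)
}

#' @export
dim.epoched_recording <- function(x) dim(x$samples)

#' Time axis of an epoch, in seconds relative to stimulus onset
#' @param rec an `epoched_recording`.
#' @return numeric vector of length `dim(rec)[3]`.
#' @export
epoch_times <- function(rec) rec$time0 + (seq_len(dim(rec$samples)[3]) - 1) / rec$fs

#' Segment a continuous multichannel signal into equal epochs
#'
#' @param x numeric matrix `[channel, time]`.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch length in seconds (default 2, the resting-analysis
#'   segment length giving 0.5 Hz spectral steps).
#' @return array `[channel, epoch, time]`; trailing partial epochs dropped.
#' @export
segment_epochs <- function(x, fs, epoch_s = 2) {
  n_ep_samp <- round(fs * epoch_s)
  n_ep <- floor(ncol(x) / n_ep_samp)
  if (n_ep < 1) stop_fx("signal shorter than one %g s epoch", epoch_s)
  out <- array(0, dim = c(nrow(x), n_ep, n_ep_samp))
  for (e in seq_len(n_ep))
    out[, e, ] <- x[, ((e - 1) * n_ep_samp + 1):(e * n_ep_samp), drop = FALSE]
  out
}

#' Write / read an epoched recording as plain text
#'
#' Artifact boundary for numeric-array EEG: a TSV whose first column gives
#' the channel label and epoch index and remaining columns the samples, with
#' a commented header carrying sampling rate, montage, task and `time0`.
#'
#' @param rec an `epoched_recording`.
#' @param path file path.
#' @return `read_recording` returns an `epoched_recording`;
#'   `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  d <- dim(rec$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g montage=%s task=%s time0=%.10g channels=%d epochs=%d samples=%d",
                     rec$fs, rec$montage, rec$task, rec$time0, d[1], d[2], d[3]), con)
  for (ch in seq_len(d[1])) for (e in seq_len(d[2]))
    writeLines(paste(c(rec$labels[ch], e,
                       formatC(rec$samples[ch, e, ], format = "g", digits = 10)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- do.call(rbind, strsplit(hdr, "="))
  h <- stats::setNames(kv[, 2], kv[, 1])
  d <- as.integer(c(h["channels"], h["epochs"], h["samples"]))
  samples <- array(0, dim = d)
  labels <- character(d[1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  i <- 0L
  for (ch in seq_len(d[1])) for (e in seq_len(d[2])) {
    i <- i + 1L
    row <- body[[i]]
    labels[ch] <- row[1]
    samples[ch, e, ] <- as.numeric(row[-(1:2)])
  }
  epoched_recording(samples, fs = as.numeric(h["fs"]), labels = labels,
                    montage = unname(h["montage"]), task = unname(h["task"]),
                    time0 = as.numeric(h["time0"]))
}
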