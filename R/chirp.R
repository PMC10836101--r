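# Chirp-trial time-frequency analysis: fronto-central cluster average,
# Morlet wavelet transform with a linearly increasing cycle count,
# inter-trial phase coherence (ITPC), single-trial power (STP), and the
# seven chirp variables read off rectangular and chirp-diagonal
# time-frequency regions of interest.

#' Average trials across a sensor cluster
#'
#' @param rec a chirp [epoched_recording()] (channels x trials x time).
#' @param cluster channel labels to average; all must exist in `rec`.
#' @return matrix trials x time with attributes `fs` and `times`
#'   (s relative to stimulus onset).
#' @export
cluster_average <- function(rec, cluster = intersect(chirp_cluster(), rec$labels)) {
  if (length(cluster) == 0) stop_fx("empty sensor cluster")
  missing <- setdiff(cluster, rec$labels)
  if (length(missing) > 0)
    stop_fx("cluster channels absent: %s", paste(missing, collapse = ", "))
  idx <- match(cluster, rec$labels)
  d <- dim(rec$samples)
  out <- matrix(0, d[2], d[3])
  for (ch in idx) out <- out + rec$samples[ch, , , drop = TRUE]
  out <- out / length(idx)
  if (d[2] == 1) out <- matrix(out, nrow = 1)
  attr(out, "fs") <- rec$fs
  attr(out, "times") <- epoch_times(rec)
  out
}

#' Cycle count of the Morlet family at each frequency
#'
#' Linear from 1 cycle at the lowest analyzed frequency to 30 at the
#' highest: `1 + 29 * (f - fmin) / (fmax - fmin)`.
#'
#' @param freqs analyzed frequencies, Hz.
#' @return numeric vector of cycle counts.
#' @export
morlet_cycles <- function(freqs) {
  if (length(freqs) == 1) return(7)  # degenerate single-frequency grid
  1 + 29 * (freqs - min(freqs)) / (max(freqs) - min(freqs))
}

#' Morlet wavelet transform of trial signals
#'
#' Complex convolution of each trial with Gaussian-windowed complex
#' exponentials; wavelets are amplitude-normalized so a sinusoid of
#' amplitude A microvolts at an analyzed frequency yields |coefficient| = A
#' (hence |coefficient|^2 = A^2, microvolts squared). Samples within half a
#' wavelet of either trial edge are marked invalid (NA) since the
#' convolution there overruns the trial.
#'
#' @param x matrix trials x time (e.g. from [cluster_average()]) with `fs`
#'   and `times` attributes, or supply `fs`/`times` explicitly.
#' @param freqs analyzed frequency grid, Hz (default 2-100 at 1 Hz steps).
#' @param fs sampling rate, Hz.
#' @param times sample times, s relative to onset.
#' @param tstep time resolution of the stored coefficients, s (the
#'   convolution runs at full rate; coefficients are kept on this decimated
#'   grid to bound memory).
#' @return object of class `tf_cube`: list with `coef` (complex array
#'   trials x freqs x times), `freqs`, `times`, `cycles`, and `valid`
#'   (freqs x times logical).
#' @export
morlet_transform <- function(x, freqs = 2:100,
                             fs = attr(x, "fs"), times = attr(x, "times"),
                             tstep = 0.01) {
  stopifnot(is.matrix(x), !is.null(fs), !is.null(times))
  if (fs < 2 * max(freqs))
    stop_fx("sampling rate %g Hz below Nyquist for %g Hz", fs, max(freqs))
  n <- ncol(x)
  ntr <- nrow(x)
  cycles <- morlet_cycles(freqs)
  sigma <- cycles / (2 * pi * freqs)
  halflen <- ceiling(3 * sigma * fs)
  if (any(2 * halflen + 1 > n)) {
    f_bad <- freqs[which.max(2 * halflen + 1 > n)]
    stop_fx("trial (%d samples) shorter than the %g Hz wavelet", n, f_bad)
  }

  keep <- seq(1, n, by = max(1L, round(tstep * fs)))
  nfft <- stats::nextn(n + max(2 * halflen + 1), 2)
  xf <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, ntr))) # nfft x ntr

  coef <- array(NA_complex_, dim = c(ntr, length(freqs), length(keep)))
  valid <- matrix(TRUE, length(freqs), length(keep))
  for (k in seq_along(freqs)) {
    L <- halflen[k]
    tt <- (-L:L) / fs
    env <- exp(-tt^2 / (2 * sigma[k]^2))
    wav <- env * exp(2i * pi * freqs[k] * tt) / (sum(env) / 2)
    wf <- stats::fft(c(wav, rep(0, nfft - length(wav))))
    conv <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
    full <- t(conv[(L + 1):(L + n), , drop = FALSE])        # ntr x n, centered
    coef[, k, ] <- full[, keep, drop = FALSE]
    bad <- keep <= L | keep > n - L
    valid[k, bad] <- FALSE
    coef[, k, bad] <- NA_complex_
  }
  structure(list(coef = coef, freqs = freqs, times = times[keep],
                 cycles = cycles, valid = valid),
            class = "tf_cube")
}

#' Inter-trial phase coherence map
#'
#' Resultant length of the unit phase vectors across trials at each valid
#' time-frequency point: 1 for perfectly phase-locked trials, about
#' sqrt(pi)/(2 sqrt(N)) in expectation for N uniform-phase trials.
#' Zero-magnitude coefficients carry no phase and are excluded with a
#' message.
#'
#' @param cube a [morlet_transform()] result with >= 2 trials.
#' @return matrix freqs x times in [0, 1]; NA at invalid edge points.
#' @export
itpc <- function(cube) {
  stopifnot(inherits(cube, "tf_cube"))
  if (dim(cube$coef)[1] < 2) stop_fx("ITPC needs at least 2 trials")
  m <- Mod(cube$coef)
  zero <- m == 0 & !is.na(m)
  if (any(zero))
    message(sprintf("itpc: excluded %d zero-magnitude coefficient(s)", sum(zero)))
  u <- cube$coef / m
  u[zero] <- NA_complex_
  res <- apply(u, c(2, 3), function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) return(NA_real_)
    Mod(mean(z))
  })
  dimnames(res) <- list(cube$freqs, NULL)
  res
}

#' Single-trial power map
#'
#' Mean over trials of squared coefficient magnitude, scaled to
#' 10 log10(microvolts squared). With a `baseline` window (pre-onset), the
#' per-frequency mean log baseline power is subtracted, so post-onset
#' desynchronization yields negative values.
#'
#' @param cube a [morlet_transform()] result.
#' @param baseline optional length-2 time window (s, must lie pre-onset).
#' @return matrix freqs x times (dB); NA at invalid edge points.
#' @export
single_trial_power <- function(cube, baseline = NULL) {
  stopifnot(inherits(cube, "tf_cube"))
  p <- apply(Mod(cube$coef)^2, c(2, 3), mean)
  logp <- 10 * log10(p)
  if (!is.null(baseline)) {
    if (baseline[2] > 0) stop_fx("baseline window overlaps the stimulus")
    bix <- which(cube$times >= baseline[1] & cube$times <= baseline[2])
    if (length(bix) == 0) stop_fx("baseline window contains no valid samples")
    logp <- logp - rowMeans(logp[, bix, drop = FALSE], na.rm = TRUE)
  }
  dimnames(logp) <- list(cube$freqs, NULL)
  logp
}

#' Default time-frequency regions of interest for the chirp variables
#'
#' Rectangular windows for the onset/offset ITPC and the STP variables;
#' chirp-diagonal masks (tracking the instantaneous sweep frequency
#' f(t) = sweep_rate * t within +/- `half_bw` Hz) for the low- and
#' high-gamma chirp ITPC. The evoked alpha ROI is baseline-corrected
#' against the pre-stimulus window.
#'
#' @param sweep_rate chirp sweep rate, Hz/s.
#' @param trial_window length-2 trial time range, s (defaults to the
#'   standard -0.5 to 2.5 s window).
#' @return tibble: `name`, `measure` (`itpc`/`stp`), `kind`
#'   (`rectangle`/`chirp_diagonal`), `fmin`, `fmax`, `tmin`, `tmax`,
#'   `half_bw`, `baseline_lo`, `baseline_hi`.
#' @export
chirp_rois <- function(sweep_rate = 50, trial_window = c(-0.5, 2.5)) {
  tibble::tibble(
    name    = c("Gamma Power", "Theta Power", "Alpha Power",
                "Low Gamma ITPC", "High Gamma ITPC",
                "Stimulus Onset ITPC", "Stimulus Offset ITPC"),
    measure = c("stp", "stp", "stp", "itpc", "itpc", "itpc", "itpc"),
    kind    = c("rectangle", "rectangle", "rectangle",
                "chirp_diagonal", "chirp_diagonal", "rectangle", "rectangle"),
    fmin = c(30, 4,  8, 30, 70, 4, 4),
    fmax = c(90, 8, 13, 50, 90, 13, 13),
    tmin = c(trial_window[1], trial_window[1], 0, 0.6, 1.4, 0, 2.0),
    tmax = c(trial_window[2], trial_window[2], 2, 1.0, 1.8, 0.5, 2.5),
    half_bw = c(NA, NA, NA, 10, 10, NA, NA),
    baseline_lo = c(NA, NA, -0.5, NA, NA, NA, NA),
    baseline_hi = c(NA, NA, 0, NA, NA, NA, NA)
  )
}

.roi_mask <- function(cube, roi, sweep_rate) {
  fin <- cube$freqs >= roi$fmin & cube$freqs <= roi$fmax
  tin <- cube$times >= roi$tmin & cube$times <= roi$tmax
  mask <- outer(fin, tin)
  if (roi$kind == "chirp_diagonal") {
    diag_ok <- abs(outer(cube$freqs, sweep_rate * cube$times, `-`)) <= roi$half_bw
    mask <- mask & diag_ok
  }
  mask & cube$valid
}

#' Extract the seven chirp variables
#'
#' Averages the ITPC map or STP map (baseline-corrected for the evoked
#' alpha ROI) over each region of interest's valid points.
#'
#' @param cube a [morlet_transform()] result.
#' @param rois ROI tibble (default [chirp_rois()]).
#' @param sweep_rate sweep rate used by the diagonal masks, Hz/s.
#' @return named numeric vector of length 7, in the report's row order.
#' @export
extract_chirp_variables <- function(cube, rois = chirp_rois(), sweep_rate = 50) {
  itpc_map <- itpc(cube)
  stp_map <- single_trial_power(cube)
  out <- stats::setNames(numeric(nrow(rois)), rois$name)
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    map <- if (roi$measure == "itpc") itpc_map
           else if (!is.na(roi$baseline_lo))
             single_trial_power(cube, c(roi$baseline_lo, roi$baseline_hi))
           else stp_map
    mask <- .roi_mask(cube, roi, sweep_rate)
    vals <- map[mask]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) stop_fx("ROI '%s' has no valid points", roi$name)
    out[roi$name] <- mean(vals)
  }
  out
}

#' The seven chirp variables of one recording
#'
#' Pipeline composition: cluster average, Morlet transform, ROI extraction.
#'
#' @param rec a chirp [epoched_recording()].
#' @param cluster sensor cluster labels.
#' @param freqs analyzed frequency grid, Hz.
#' @param rois ROI tibble.
#' @param sweep_rate sweep rate, Hz/s.
#' @return named numeric vector of length 7.
#' @export
chirp_feature_vector <- function(rec, cluster = intersect(chirp_cluster(), rec$labels),
                                 freqs = 2:100, rois = chirp_rois(),
                                 sweep_rate = 50) {
  x <- cluster_average(rec, cluster)
  cube <- morlet_transform(x, freqs = freqs)
  extract_chirp_variables(cube, rois, sweep_rate)
}
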