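# Resting-state spectral variables: amplitude spectra on a 0.5 Hz grid,
# absolute/relative band power over seven bands and three scalp regions, and
# peak alpha frequency — 45 variables per recording.

#' Default frequency band definitions
#'
#' Seven conventional bands; low edge inclusive, high edge exclusive.
#' The 55-65 Hz gap between the gamma bands is excluded from analysis as a
#' line-noise notch, so the relative-power denominator runs over the union
#' of the seven bands only.
#'
#' @return tibble with columns `band` (report label), `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("Delta", "Theta", "Alpha 1", "Alpha 2", "Beta", "Gamma 1", "Gamma 2"),
    low  = c(1, 4, 8, 10, 13, 30, 65),
    high = c(4, 8, 10, 13, 30, 55, 90)
  )
}

.check_bands <- function(bands) {
  stopifnot(all(c("band", "low", "high") %in% names(bands)))
  o <- order(bands$low)
  b <- bands[o, ]
  if (any(b$high <= b$low)) stop_fx("band with nonpositive width")
  if (any(b$low[-1] < b$high[-nrow(b)])) stop_fx("overlapping bands")
  invisible(b)
}

#' Region-averaged amplitude spectrum of a resting recording
#'
#' Per epoch and channel, the single-sided magnitude spectrum of the
#' Hann-windowed 2 s epoch on the 0.5 Hz grid (window-amplitude-corrected, so
#' a grid-aligned sinusoid of amplitude A microvolts peaks at A); averaged
#' over epochs, then over each region's channels. Epochs containing
#' non-finite samples are dropped with a message.
#'
#' @param rec an [epoched_recording()] with 2 s epochs.
#' @param regions named list of channel-label sets (see [region_map()]).
#' @return object of class `amplitude_spectrum`: list with `frequencies`
#'   (Hz, 0.5 Hz steps, DC excluded) and `amplitude` (regions x frequencies
#'   matrix, microvolts).
#' @export
amplitude_spectrum <- function(rec, regions) {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- dim(rec$samples)
  nsamp <- d[3]
  if (abs(rec$fs / nsamp - 0.5) > 1e-9)
    stop_fx("epoch length (%d samples @ %g Hz) does not give 0.5 Hz steps",
            nsamp, rec$fs)
  for (rn in names(regions)) {
    if (length(regions[[rn]]) == 0) stop_fx("empty region '%s'", rn)
    missing <- setdiff(regions[[rn]], rec$labels)
    if (length(missing) > 0)
      stop_fx("region '%s' channels absent: %s", rn, paste(missing, collapse = ", "))
  }

  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nsamp) - 1) / nsamp))  # Hann
  scale <- 2 / sum(w)
  nfreq <- floor(nsamp / 2)
  freqs <- (seq_len(nfreq)) * rec$fs / nsamp

  # per-channel spectra averaged over finite epochs
  ch_amp <- matrix(0, d[1], nfreq)
  dropped <- 0L
  for (ch in seq_len(d[1])) {
    acc <- numeric(nfreq)
    used <- 0L
    for (e in seq_len(d[2])) {
      x <- rec$samples[ch, e, ]
      if (!all(is.finite(x))) { dropped <- dropped + 1L; next }
      sp <- stats::fft(x * w)
      acc <- acc + Mod(sp[2:(nfreq + 1)]) * scale
      used <- used + 1L
    }
    if (used == 0L) stop_fx("all epochs dropped for channel %s", rec$labels[ch])
    ch_amp[ch, ] <- acc / used
  }
  if (dropped > 0L)
    message(sprintf("amplitude_spectrum: dropped %d non-finite epoch(s)", dropped))

  amp <- t(vapply(regions, function(set) {
    colMeans(ch_amp[match(set, rec$labels), , drop = FALSE])
  }, numeric(nfreq)))
  structure(list(frequencies = freqs, amplitude = amp),
            class = "amplitude_spectrum")
}

.band_bins <- function(freqs, low, high) which(freqs >= low & freqs < high)

#' Band power per region
#'
#' Absolute mode sums the spectral amplitude over the band's bins and scales
#' the microvolt amplitudes by `pv_scale` for reporting on the picovolt
#' scale; relative mode divides the band sum by the total over all analyzed
#' bins (the union of the bands — the notch gap never enters the
#' denominator), giving proportions in [0, 1] that sum to 1 across bands.
#'
#' @param spec an [amplitude_spectrum()].
#' @param bands band definition tibble (default [band_definitions()]).
#' @param mode `"absolute"` or `"relative"`.
#' @param pv_scale microvolt-to-report scale for absolute mode (default 1e6).
#' @return matrix regions x bands.
#' @export
band_power <- function(spec, bands = band_definitions(),
                       mode = c("absolute", "relative"), pv_scale = 1e6) {
  mode <- match.arg(mode)
  .check_bands(bands)
  bins <- lapply(seq_len(nrow(bands)),
                 function(i) .band_bins(spec$frequencies, bands$low[i], bands$high[i]))
  if (any(lengths(bins) == 0)) stop_fx("band outside the spectrum's frequency grid")
  sums <- vapply(bins, function(ix) rowSums(spec$amplitude[, ix, drop = FALSE]),
                 numeric(nrow(spec$amplitude)))
  if (is.null(dim(sums))) sums <- matrix(sums, nrow = 1)
  dimnames(sums) <- list(rownames(spec$amplitude), bands$band)
  if (mode == "absolute") return(sums * pv_scale)
  tot <- rowSums(sums)
  if (any(tot <= 0)) stop_fx("zero total power: relative band power undefined")
  sweep(sums, 1, tot, `/`)
}

#' Peak alpha frequency
#'
#' The frequency on the 0.5 Hz grid at which log spectral power is maximal
#' within `window` (default 6-14 Hz) for the requested region. Ties break
#' toward the lower frequency. A maximum at either window edge — the
#' signature of a monotone 1/f spectrum without an alpha rhythm — triggers
#' an "edge-peak" warning.
#'
#' @param spec an [amplitude_spectrum()].
#' @param region region name (row of the spectrum).
#' @param window numeric length-2 search window, Hz (inclusive).
#' @return peak frequency in Hz.
#' @export
peak_alpha_frequency <- function(spec, region = "posterior", window = c(6, 14)) {
  ix <- which(spec$frequencies >= window[1] & spec$frequencies <= window[2])
  if (length(ix) == 0) stop_fx("frequency grid does not cover [%g, %g] Hz",
                               window[1], window[2])
  a <- spec$amplitude[region, ix]
  if (all(a == 0)) stop_fx("spectrum is zero throughout the alpha window")
  k <- which.max(log(a^2 + .Machine$double.xmin))  # first max -> lower-frequency tie-break
  if (k == 1L || k == length(ix))
    warning("edge-peak: alpha-window maximum at the window boundary", call. = FALSE)
  spec$frequencies[ix[k]]
}

#' The 45 resting-state variables of one recording
#'
#' 7 bands x {absolute, relative} x {frontal, posterior, whole-head} = 42
#' band-power values plus peak alpha frequency in each of the three regions.
#' Names carry a family prefix (`"Absolute "`, `"Relative "`,
#' `"Alpha Peak "`) followed by the report row label (e.g.
#' `"Relative Frontal Theta"`, `"Alpha Peak Posterior"`), so the vector's 45
#' names are unique while each family restricts to the bare report labels.
#'
#' @param rec an [epoched_recording()] (resting task).
#' @param regions named list with `frontal`, `posterior`, `whole_head`.
#' @param bands band definitions (default [band_definitions()]).
#' @return named numeric vector of length 45.
#' @export
resting_feature_vector <- function(rec, regions = region_map("hydrocel128", rec$labels),
                                   bands = band_definitions()) {
  spec <- amplitude_spectrum(rec, regions)
  region_label <- c(frontal = "Frontal", posterior = "Posterior",
                    whole_head = "Whole Head")[names(regions)]
  absm <- band_power(spec, bands, "absolute")
  relm <- band_power(spec, bands, "relative")
  out <- c()
  for (m in list(list(tag = "Absolute", v = absm), list(tag = "Relative", v = relm))) {
    for (r in seq_along(region_label)) for (b in seq_len(nrow(bands))) {
      out[paste(m$tag, region_label[r], bands$band[b])] <- m$v[r, b]
    }
  }
  for (r in seq_along(region_label)) {
    out[paste("Alpha Peak", region_label[r])] <-
      peak_alpha_frequency(spec, names(regions)[r])
  }
  out
}
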