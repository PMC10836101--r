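# Signal-level EEG simulation: 1/f background + band-limited oscillators for
# resting data; onset transient + frequency-swept phase-locked response +
# desynchronizing alpha for chirp trials. Ground truth (oscillator
# amplitudes, alpha peak, phase jitter) is held by the parameter object so
# every extracted feature can be checked against the knob that generated it.

#' Parameters for resting-state EEG simulation
#'
#' Each channel is simulated as 1/f-shaped ("pink") background noise plus a
#' sum of band-limited sinusoidal oscillators — always including an alpha
#' oscillator at `alpha_freq` — plus white sensor noise, then segmented into
#' non-overlapping 2 s epochs.
#'
#' @param channels channel labels to simulate (default the dense-array
#'   working set, [hydrocel_working_set()]).
#' @param fs sampling rate, Hz.
#' @param duration continuous duration, s (segmented into 2 s epochs).
#' @param exponent spectral exponent of the 1/f background (power ~ 1/f^exponent).
#' @param pink_amp RMS amplitude of the 1/f background, microvolts.
#' @param oscillations data frame with columns `freq` (Hz) and `amp`
#'   (microvolts): additional band-limited oscillators.
#' @param alpha_freq alpha oscillator peak frequency, Hz; must lie in
#'   [6, 14], the window searched by [peak_alpha_frequency()].
#' @param alpha_amp alpha oscillator amplitude, microvolts.
#' @param noise_amp white-noise RMS amplitude, microvolts.
#' @param seed integer seed; all draws flow from one generator seeded here.
#' @return a list of class `resting_sim_params`.
#' @export
resting_sim_params <- function(channels = hydrocel_working_set(),
                               fs = 1000, duration = 20,
                               exponent = 1, pink_amp = 1,
                               oscillations = data.frame(freq = c(2.5, 6, 20),
                                                         amp  = c(0.5, 0.5, 0.2)),
                               alpha_freq = 10, alpha_amp = 1,
                               noise_amp = 0.2, seed = 1L) {
  if (alpha_freq < 6 || alpha_freq > 14)
    stop_fx("alpha_freq %.3g Hz outside [6, 14]", alpha_freq)
  if (duration <= 0) stop_fx("duration must be positive")
  top <- max(c(oscillations$freq, alpha_freq, 90))
  if (fs < 2 * top)
    stop_fx("sampling rate %g Hz below Nyquist for %g Hz content", fs, top)
  if (any(c(oscillations$amp, alpha_amp, pink_amp, noise_amp) < 0))
    stop_fx("amplitudes must be nonnegative")
  structure(list(channels = channels, fs = fs, duration = duration,
                 exponent = exponent, pink_amp = pink_amp,
                 oscillations = oscillations, alpha_freq = alpha_freq,
                 alpha_amp = alpha_amp, noise_amp = noise_amp,
                 seed = as.integer(seed)),
            class = "resting_sim_params")
}

# 1/f^(exponent) power-shaped noise, RMS-normalized to `amp`, via spectral
# shaping of white noise.
.pink_noise <- function(n, fs, exponent, amp) {
  if (amp == 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1e-12, seq_len(n - 1)) * fs / n      # guard DC
  f <- pmin(f, fs - f)                        # two-sided symmetry
  shape <- 1 / f^(exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  amp * x / stats::sd(x)
}

#' Simulate resting-state multichannel EEG
#'
#' @param params a [resting_sim_params()] object.
#' @return an [epoched_recording()] with 2 s epochs, task `"rest"`,
#'   montage `"hydrocel128"`. Deterministic under `params$seed`.
#' @export
#' @examples
#' rec <- simulate_resting_eeg(resting_sim_params(channels = c("E11", "E62"),
#'                                                fs = 250, duration = 10))
#' dim(rec)
simulate_resting_eeg <- function(params) {
  stopifnot(inherits(params, "resting_sim_params"))
  set.seed(params$seed)
  n <- round(params$fs * params$duration)
  t <- (seq_len(n) - 1) / params$fs
  nch <- length(params$channels)
  x <- matrix(0, nch, n)
  osc <- rbind(params$oscillations,
               data.frame(freq = params$alpha_freq, amp = params$alpha_amp))
  for (ch in seq_len(nch)) {
    sig <- .pink_noise(n, params$fs, params$exponent, params$pink_amp)
    for (k in seq_len(nrow(osc))) {
      if (osc$amp[k] == 0) next
      ph <- stats::runif(1, 0, 2 * pi)
      sig <- sig + osc$amp[k] * sin(2 * pi * osc$freq[k] * t + ph)
    }
    if (params$noise_amp > 0)
      sig <- sig + stats::rnorm(n, sd = params$noise_amp)
    x[ch, ] <- sig
  }
  epoched_recording(segment_epochs(x, params$fs, 2), fs = params$fs,
                    labels = params$channels, montage = "hydrocel128",
                    task = "rest")
}

#' Group presets for resting simulation
#'
#' Parameter sets reproducing the qualitative FXS-vs-control resting
#' profile: FXS carries relatively more theta, relatively less high alpha,
#' and a slower alpha peak (8.0 Hz vs 8.5 Hz on the 0.5 Hz analysis grid).
#'
#' @param group `"FXS"` or `"CON"`.
#' @param ... overrides passed to [resting_sim_params()].
#' @return a `resting_sim_params` object.
#' @export
resting_group_presets <- function(group = c("FXS", "CON"), ...) {
  group <- match.arg(group)
  base <- if (group == "FXS") {
    list(oscillations = data.frame(freq = c(2.5, 6, 20), amp = c(0.6, 0.9, 0.2)),
         alpha_freq = 8.0, alpha_amp = 0.7)
  } else {
    list(oscillations = data.frame(freq = c(2.5, 6, 20), amp = c(0.5, 0.5, 0.2)),
         alpha_freq = 8.5, alpha_amp = 1.1)
  }
  do.call(resting_sim_params, utils::modifyList(base, list(...)))
}

#' Parameters for auditory chirp-trial simulation
#'
#' Each trial contains (i) a damped low-frequency onset transient at
#' stimulus onset and offset, (ii) a chirp-following oscillation whose
#' instantaneous frequency rises linearly at `sweep_rate` Hz/s (default 50,
#' i.e. 0 to 100 Hz modulation over the 2 s stimulus) with a per-trial phase
#' offset drawn from a wrapped normal of SD `jitter_sd` (or uniform on
#' [-pi, pi) when `jitter_dist = "uniform"`), (iii) a background alpha
#' oscillator attenuated by `alpha_desync` after onset (producing negative
#' evoked alpha power), and (iv) white noise. Phase jitter applies to the
#' onset/offset transients as well, so one knob controls all four ITPC
#' variables.
#'
#' @param n_trials number of trials (the reference paradigm presents 200;
#'   inter-trial gaps, jittered 1500-2000 ms in that paradigm, do not enter
#'   the epoched simulation).
#' @param channels channel labels (default the fronto-central
#'   [chirp_cluster()]).
#' @param fs sampling rate, Hz.
#' @param pre,stim,post pre-stimulus, stimulus and post-stimulus window, s.
#' @param sweep_rate chirp sweep rate, Hz/s.
#' @param jitter_sd phase-jitter SD, radians (controls ITPC; expected
#'   resultant length of a wrapped normal is exp(-sd^2/2)).
#' @param jitter_dist `"wrapped_normal"` or `"uniform"`.
#' @param resp_amp chirp-following response amplitude, microvolts
#'   (controls gamma single-trial power).
#' @param onset_amp onset/offset transient amplitude, microvolts.
#' @param onset_freq onset transient frequency, Hz.
#' @param onset_tau onset transient decay constant, s.
#' @param alpha_amp background alpha amplitude, microvolts.
#' @param alpha_freq background alpha frequency, Hz.
#' @param alpha_desync multiplicative post-onset attenuation of the alpha
#'   oscillator (< 1 gives event-related desynchronization).
#' @param noise_amp white-noise RMS, microvolts.
#' @param seed integer seed.
#' @return a list of class `chirp_sim_params`.
#' @export
chirp_sim_params <- function(n_trials = 200, channels = chirp_cluster(),
                             fs = 1000, pre = 0.5, stim = 2, post = 0.5,
                             sweep_rate = 50, jitter_sd = 1,
                             jitter_dist = c("wrapped_normal", "uniform"),
                             resp_amp = 1, onset_amp = 2, onset_freq = 6,
                             onset_tau = 0.15, alpha_amp = 1,
                             alpha_freq = 10, alpha_desync = 0.7,
                             noise_amp = 1, seed = 1L) {
  jitter_dist <- match.arg(jitter_dist)
  if (n_trials < 1) stop_fx("need at least one trial")
  if (jitter_sd < 0) stop_fx("jitter_sd must be nonnegative")
  if (pre + stim + post < stim || stim <= 0)
    stop_fx("trial window shorter than the stimulus")
  if (fs < 2 * sweep_rate * stim)
    stop_fx("sampling rate below Nyquist for the %g Hz sweep top", sweep_rate * stim)
  structure(list(n_trials = as.integer(n_trials), channels = channels, fs = fs,
                 pre = pre, stim = stim, post = post, sweep_rate = sweep_rate,
                 jitter_sd = jitter_sd, jitter_dist = jitter_dist,
                 resp_amp = resp_amp, onset_amp = onset_amp,
                 onset_freq = onset_freq, onset_tau = onset_tau,
                 alpha_amp = alpha_amp, alpha_freq = alpha_freq,
                 alpha_desync = alpha_desync, noise_amp = noise_amp,
                 seed = as.integer(seed)),
            class = "chirp_sim_params")
}

#' Simulate auditory chirp trials
#'
#' @param params a [chirp_sim_params()] object.
#' @return an [epoched_recording()] (channels x trials x time) with task
#'   `"chirp"` and `time0 = -params$pre`. Deterministic under `params$seed`.
#' @export
simulate_chirp_trials <- function(params) {
  stopifnot(inherits(params, "chirp_sim_params"))
  set.seed(params$seed)
  fs <- params$fs
  t <- seq(-params$pre, params$stim + params$post - 1 / fs, by = 1 / fs)
  n <- length(t)
  nch <- length(params$channels)
  ntr <- params$n_trials

  phi <- switch(params$jitter_dist,
    wrapped_normal = stats::rnorm(ntr, 0, params$jitter_sd),
    uniform        = stats::runif(ntr, -pi, pi))
  alpha_phi <- stats::runif(ntr, 0, 2 * pi)

  during <- t >= 0 & t < params$stim
  after_on <- t >= 0
  off_t <- t - params$stim

  out <- array(0, dim = c(nch, ntr, n))
  for (tr in seq_len(ntr)) {
    sig <- numeric(n)
    # onset and offset transients, phase-locked up to the trial jitter
    sig <- sig + params$onset_amp * exp(-pmax(t, 0) / params$onset_tau) *
      sin(2 * pi * params$onset_freq * pmax(t, 0) + phi[tr]) * (t >= 0)
    sig <- sig + params$onset_amp * exp(-pmax(off_t, 0) / params$onset_tau) *
      sin(2 * pi * params$onset_freq * pmax(off_t, 0) + phi[tr]) * (off_t >= 0)
    # chirp-following response: instantaneous frequency sweep_rate * t
    sig[during] <- sig[during] + params$resp_amp *
      sin(pi * params$sweep_rate * t[during]^2 + phi[tr])
    # background alpha, desynchronized post-onset
    amp_a <- params$alpha_amp * ifelse(after_on, params$alpha_desync, 1)
    sig <- sig + amp_a * sin(2 * pi * params$alpha_freq * t + alpha_phi[tr])
    for (ch in seq_len(nch))
      out[ch, tr, ] <- sig + if (params$noise_amp > 0)
        stats::rnorm(n, sd = params$noise_amp) else 0
  }
  epoched_recording(out, fs = fs, labels = params$channels,
                    montage = "hydrocel128", task = "chirp",
                    time0 = -params$pre)
}
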