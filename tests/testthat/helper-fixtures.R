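# Shared fixtures: all synthetic, built in code at test time.

# A tiny single-region recording holding an arbitrary channels x time signal,
# segmented into 2 s epochs.
make_rest_rec <- function(x, fs = 250, labels = paste0("ch", seq_len(nrow(x)))) {
  epoched_recording(segment_epochs(x, fs, 2), fs = fs, labels = labels,
                    montage = "custom", task = "rest")
}

# Region map treating every channel as every region (frontal = posterior =
# whole head), for single-population spectra.
uniform_regions <- function(labels) {
  list(frontal = labels, posterior = labels, whole_head = labels)
}

# Amplitude-spectrum object with a prescribed amplitude vector on the
# 0.5 Hz grid (single region replicated across the three region rows).
make_spectrum <- function(amp, fs = 250) {
  m <- rbind(frontal = amp, posterior = amp, whole_head = amp)
  structure(list(frequencies = seq_along(amp) * 0.5, amplitude = m),
            class = "amplitude_spectrum")
}

# Time-frequency cube with prescribed complex coefficients
# (trials x freqs x times), all points valid.
make_cube <- function(coef, freqs = seq_len(dim(coef)[2]),
                      times = (seq_len(dim(coef)[3]) - 1) * 0.01) {
  structure(list(coef = coef, freqs = freqs, times = times,
                 cycles = morlet_cycles(freqs),
                 valid = matrix(TRUE, dim(coef)[2], dim(coef)[3])),
            class = "tf_cube")
}

# Two-class Gaussian feature table.
make_gauss_table <- function(n1, n0, mu1, mu0, sd1 = 1, sd0 = 1, seed = 1) {
  set.seed(seed)
  k <- length(mu1)
  x1 <- sweep(matrix(rnorm(n1 * k, sd = sd1), n1), 2, mu1, `+`)
  x0 <- sweep(matrix(rnorm(n0 * k, sd = sd0), n0), 2, mu0, `+`)
  X <- rbind(x1, x0)
  colnames(X) <- paste0("f", seq_len(k))
  tibble::tibble(participant = sprintf("P%03d", seq_len(n1 + n0)),
                 group = rep(c("FXS", "CON"), c(n1, n0)),
                 sex = "M", mosaic = FALSE, tibble::as_tibble(X))
}
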