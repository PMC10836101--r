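test_that("a grid-aligned sinusoid concentrates at its bin with the window's spread", {
  fs <- 250
  t <- (0:(fs * 2 - 1)) / fs
  x <- matrix(3 * sin(2 * pi * 10 * t), 1)
  rec <- make_rest_rec(x, fs, "c1")
  spec <- amplitude_spectrum(rec, uniform_regions("c1"))
  pk <- which.max(spec$amplitude["frontal", ])
  expect_equal(spec$frequencies[pk], 10)
  expect_equal(unname(spec$amplitude["frontal", pk]), 3, tolerance = 1e-9)
  away <- abs(spec$frequencies - 10) > 0.5
  expect_lt(max(spec$amplitude["frontal", away]), 3 * 1e-9)
  # Hann total: main bin + two half-amplitude side bins = 2A within 5%
  expect_equal(sum(spec$amplitude["frontal", ]), 6, tolerance = 0.05 * 6)
})

test_that("epoch averaging is linear in per-epoch amplitudes", {
  fs <- 250
  t <- (0:(fs * 2 - 1)) / fs
  x <- matrix(c(sin(2 * pi * 10 * t), 3 * sin(2 * pi * 10 * t)), 1)
  rec <- make_rest_rec(x, fs, "c1")
  spec <- amplitude_spectrum(rec, uniform_regions("c1"))
  expect_equal(unname(spec$amplitude["frontal", spec$frequencies == 10]), 2,
               tolerance = 1e-9)
})

test_that("white-noise spectra are flat within 2 percent at long run lengths", {
  set.seed(42)
  fs <- 250
  x <- matrix(rnorm(fs * 2 * 10000), 1)
  rec <- make_rest_rec(x, fs, "c1")
  spec <- amplitude_spectrum(rec, uniform_regions("c1"))
  ix <- spec$frequencies >= 1 & spec$frequencies <= 90
  a <- spec$amplitude["frontal", ix]
  expect_lt((max(a) - min(a)) / mean(a), 0.04)   # +/- 2% about the mean
})

test_that("epoch lengths inconsistent with 0.5 Hz resolution are rejected", {
  x <- array(rnorm(2 * 3 * 100), c(2, 3, 100))
  rec <- epoched_recording(x, fs = 250, labels = c("a", "b"))
  expect_error(amplitude_spectrum(rec, uniform_regions(c("a", "b"))), "0.5 Hz")
  rec2 <- make_rest_rec(matrix(rnorm(1000), 2), 250, c("a", "b"))
  expect_error(amplitude_spectrum(rec2, list(frontal = character(0))), "empty region")
})

test_that("relative band values partition to one and count flat-spectrum bins", {
  spec <- make_spectrum(rep(1, 250))          # flat to 125 Hz on the 0.5 grid
  rel <- band_power(spec, mode = "relative")
  expect_equal(unname(rowSums(rel)), rep(1, 3), tolerance = 1e-9)
  b <- band_definitions()
  nbins <- vapply(seq_len(nrow(b)), function(i)
    sum(spec$frequencies >= b$low[i] & spec$frequencies < b$high[i]), numeric(1))
  expect_equal(unname(rel["frontal", ]), nbins / sum(nbins), tolerance = 1e-12)
  # notch gap 55-65 Hz is excluded from the denominator entirely
  expect_equal(sum(nbins), sum(spec$frequencies >= 1 & spec$frequencies < 90) -
                 sum(spec$frequencies >= 55 & spec$frequencies < 65))
})

test_that("zero total power makes relative band power an error", {
  spec <- make_spectrum(rep(0, 250))
  expect_error(band_power(spec, mode = "relative"), "zero total power")
})

test_that("peak alpha frequency takes the argmax with a lower-frequency tie-break", {
  amp <- rep(0.1, 250)
  amp[16] <- 2; amp[24] <- 1                  # 8 Hz > 12 Hz
  expect_equal(peak_alpha_frequency(make_spectrum(amp)), 8)
  amp[24] <- 2                                # exact tie 8 vs 12 -> 8
  expect_equal(peak_alpha_frequency(make_spectrum(amp)), 8)
})

test_that("a monotone spectrum pins the alpha peak at the edge with a warning", {
  spec <- make_spectrum(1 / (seq_len(250) * 0.5))
  expect_warning(pf <- peak_alpha_frequency(spec), "edge-peak")
  expect_equal(pf, 6)
  expect_error(peak_alpha_frequency(make_spectrum(rep(0, 250))), "zero")
})

test_that("the resting feature vector has 45 uniquely named variables", {
  p <- resting_sim_params(channels = c("E11", "E62"), fs = 250, duration = 6, seed = 1)
  rec <- simulate_resting_eeg(p)
  v <- resting_feature_vector(rec, uniform_regions(rec$labels))
  expect_length(v, 45)
  expect_equal(anyDuplicated(names(v)), 0)
  expect_equal(sum(startsWith(names(v), "Absolute")), 21)
  expect_equal(sum(startsWith(names(v), "Relative")), 21)
  expect_equal(sum(startsWith(names(v), "Alpha Peak")), 3)
  # identical region definitions give identical frontal and posterior values
  expect_equal(unname(v["Relative Frontal Theta"]),
               unname(v["Relative Posterior Theta"]))
})

test_that("features are invariant to channel order and scale appropriately", {
  p <- resting_sim_params(channels = c("E11", "E62"), fs = 250, duration = 6, seed = 2)
  rec <- simulate_resting_eeg(p)
  regions <- list(frontal = "E11", posterior = "E62",
                  whole_head = c("E11", "E62"))
  v1 <- resting_feature_vector(rec, regions)

  perm <- epoched_recording(rec$samples[2:1, , ], rec$fs, rec$labels[2:1],
                            task = "rest")
  expect_equal(resting_feature_vector(perm, regions), v1, tolerance = 1e-12)

  scaled <- epoched_recording(rec$samples * 3, rec$fs, rec$labels, task = "rest")
  v3 <- resting_feature_vector(scaled, regions)
  rel <- grepl("^(Relative|Alpha Peak)", names(v1))
  expect_equal(v3[rel], v1[rel], tolerance = 1e-9)
  expect_equal(unname(v3[!rel]), unname(3 * v1[!rel]), tolerance = 1e-9)
})

test_that("alpha peak recovery is exact across grid-aligned generator settings", {
  for (f0 in c(8.0, 8.5, 10.0, 12.5)) {
    p <- resting_sim_params(channels = "E11", fs = 250, duration = 12,
                            oscillations = data.frame(freq = numeric(0), amp = numeric(0)),
                            alpha_freq = f0, alpha_amp = 2, pink_amp = 0.2,
                            noise_amp = 0.05, seed = 20 + f0 * 2)
    spec <- amplitude_spectrum(simulate_resting_eeg(p), uniform_regions("E11"))
    expect_equal(peak_alpha_frequency(spec, "whole_head"), f0)
  }
})

test_that("non-finite epochs are dropped with a message", {
  fs <- 250
  x <- matrix(rnorm(fs * 4), 1)
  x[1, 600] <- NA
  rec <- make_rest_rec(x, fs, "c1")
  expect_message(spec <- amplitude_spectrum(rec, uniform_regions("c1")), "dropped 1")
  expect_true(all(is.finite(spec$amplitude)))
})
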