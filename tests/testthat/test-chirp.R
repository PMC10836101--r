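test_that("cluster averaging is a label-based linear mean", {
  x <- array(rnorm(3 * 2 * 50), c(3, 2, 50))
  rec <- epoched_recording(x, fs = 100, labels = c("a", "b", "c"),
                           task = "chirp", time0 = 0)
  one <- cluster_average(rec, "b")
  expect_equal(one[1, ], x[2, 1, ])
  arr <- array(0, c(2, 2, 50))
  arr[1, , ] <- x[1, , ]
  arr[2, , ] <- -x[1, , ]
  anti <- epoched_recording(arr, fs = 100, labels = c("p", "n"), task = "chirp")
  expect_equal(max(abs(cluster_average(anti, c("p", "n")))), 0)
  expect_equal(cluster_average(rec, c("a", "c")), cluster_average(rec, c("c", "a")))
  expect_error(cluster_average(rec, character(0)), "empty")
  expect_error(cluster_average(rec, "zz"), "zz")
})

test_that("the Morlet cycle count is linear from 1 to 30 across any grid", {
  for (freqs in list(2:100, seq(5, 45, 2), c(3, 10, 80))) {
    cyc <- morlet_cycles(freqs)
    expect_equal(cyc[1], 1)
    expect_equal(cyc[length(cyc)], 30)
    mid <- (min(freqs) + max(freqs)) / 2
    expect_equal(morlet_cycles(c(min(freqs), mid, max(freqs)))[2], 15.5)
  }
})

test_that("a pure sinusoid gives a flat unit-amplitude ridge at its frequency", {
  fs <- 500
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- matrix(sin(2 * pi * 40 * t), 1)
  attr(x, "fs") <- fs; attr(x, "times") <- t - 0.5
  cube <- morlet_transform(x, freqs = seq(10, 90, 5))
  pw <- apply(Mod(cube$coef[1, , ])^2, 1, mean, na.rm = TRUE)
  expect_equal(cube$freqs[which.max(pw)], 40)
  ridge <- Mod(cube$coef[1, cube$freqs == 40, cube$valid[cube$freqs == 40, ]])
  expect_lt(stats::sd(ridge) / mean(ridge), 0.01)     # flat over valid times
  expect_equal(mean(ridge), 1, tolerance = 0.01)      # amplitude-normalized

  x2 <- x * 2
  attr(x2, "fs") <- fs; attr(x2, "times") <- t - 0.5
  cube2 <- morlet_transform(x2, freqs = seq(10, 90, 5))
  r <- Mod(cube2$coef[1, cube2$freqs == 40, ])^2 / Mod(cube$coef[1, cube$freqs == 40, ])^2
  expect_equal(unname(r[cube$valid[cube$freqs == 40, ]]),
               rep(4, sum(cube$valid[cube$freqs == 40, ])), tolerance = 1e-6)
})

test_that("trials shorter than the longest wavelet are rejected by frequency", {
  x <- matrix(rnorm(200), 1)
  attr(x, "fs") <- 500; attr(x, "times") <- (0:199) / 500
  expect_error(morlet_transform(x, freqs = 2:40), "2 Hz")
})

test_that("ITPC is 1 for identical trials and 0 for antipodal phases", {
  coef <- array(rep(complex(modulus = 2, argument = 0.7), 4 * 3 * 5), c(4, 3, 5))
  expect_true(all(itpc(make_cube(coef)) == 1))
  anti <- array(c(exp(1i * 1.1), exp(1i * (1.1 + pi))), c(2, 1, 1))
  expect_equal(as.vector(itpc(make_cube(anti))), 0, tolerance = 1e-12)
  one <- array(1 + 0i, c(1, 2, 2))
  expect_error(itpc(make_cube(one)), "2 trials")
})

test_that("uniform-phase ITPC matches the analytic resultant-length expectation", {
  set.seed(101)
  npts <- 1200
  for (N in c(25, 100, 400)) {
    coef <- array(exp(1i * runif(N * npts, -pi, pi)), c(N, npts, 1))
    vals <- itpc(make_cube(coef))[, 1]
    expected <- sqrt(pi) / (2 * sqrt(N))
    tol <- 4 * stats::sd(vals) / sqrt(npts) + 0.002  # MC error + finite-N bias
    expect_lt(abs(mean(vals) - expected), tol)
  }
})

test_that("ITPC ignores per-trial amplitude scaling; STP ignores phase", {
  set.seed(5)
  coef <- array(complex(modulus = runif(60, 0.5, 2), argument = rnorm(60)),
                c(5, 4, 3))
  cube <- make_cube(coef)
  gains <- runif(5, 0.1, 10)
  scaled <- make_cube(coef * gains)       # recycles over the trial dimension
  expect_equal(itpc(scaled), itpc(cube), tolerance = 1e-12)

  phases <- exp(1i * runif(5, -pi, pi))
  rot <- make_cube(coef * phases)
  expect_equal(single_trial_power(rot), single_trial_power(cube), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(itpc(rot), itpc(cube), tolerance = 1e-3)))
})

test_that("zero-magnitude coefficients are excluded with a message", {
  coef <- array(exp(1i * rnorm(12)), c(4, 3, 1))
  coef[2, 1, 1] <- 0 + 0i
  expect_message(m <- itpc(make_cube(coef)), "1 zero-magnitude")
  expect_true(all(m >= 0 & m <= 1))
})

test_that("baseline correction zeroes stationary power and tracks amplitude ratios", {
  coef <- array(complex(modulus = 1.5, argument = 0), c(3, 2, 10))
  cube <- make_cube(coef, times = seq(-0.45, 0.45, by = 0.1))
  corr <- single_trial_power(cube, baseline = c(-0.45, -0.05))
  expect_equal(max(abs(corr)), 0, tolerance = 1e-12)
  expect_error(single_trial_power(cube, baseline = c(-0.1, 0.2)), "overlaps")

  up <- single_trial_power(make_cube(coef * 2, times = cube$times))
  base <- single_trial_power(cube)
  expect_equal(unname(up - base), matrix(10 * log10(4), 2, 10), tolerance = 1e-9)
})

test_that("phase-locked noise-free chirps give unit low-gamma chirp ITPC", {
  p <- chirp_sim_params(n_trials = 6, channels = "A", fs = 500, jitter_sd = 0,
                        noise_amp = 0, alpha_amp = 0, seed = 1)
  v <- chirp_feature_vector(simulate_chirp_trials(p), cluster = "A",
                            freqs = seq(2, 100, 2))
  expect_length(v, 7)
  expect_equal(names(v), chirp_rois()$name)
  expect_equal(unname(v["Low Gamma ITPC"]), 1, tolerance = 1e-6)
  expect_equal(unname(v["High Gamma ITPC"]), 1, tolerance = 1e-6)
})

test_that("all-noise trials keep every ITPC variable below the null bound", {
  N <- 60
  p <- chirp_sim_params(n_trials = N, channels = "A", fs = 500, resp_amp = 0,
                        onset_amp = 0, alpha_amp = 0, noise_amp = 1, seed = 2)
  v <- chirp_feature_vector(simulate_chirp_trials(p), cluster = "A",
                            freqs = seq(2, 100, 2))
  bound <- 3 * sqrt(pi) / (2 * sqrt(N))
  for (nm in grep("ITPC", names(v), value = TRUE))
    expect_lt(v[[nm]], bound)
})

test_that("post-onset alpha attenuation yields negative evoked alpha power", {
  p <- chirp_sim_params(n_trials = 30, channels = "A", fs = 500,
                        alpha_amp = 2, alpha_desync = 0.6, resp_amp = 0.5,
                        onset_amp = 0.5, noise_amp = 0.3, seed = 3)
  v <- chirp_feature_vector(simulate_chirp_trials(p), cluster = "A",
                            freqs = seq(2, 100, 2))
  expect_lt(v[["Alpha Power"]], 0)
})

test_that("ITPC decreases monotonically with phase-jitter SD", {
  jitters <- c(0, 0.5, 1, 1.5, 2.5)
  vals <- vapply(jitters, function(js) {
    p <- chirp_sim_params(n_trials = 40, channels = "A", fs = 500,
                          jitter_sd = js, noise_amp = 0.3, alpha_amp = 0.5,
                          seed = 17)
    v <- chirp_feature_vector(simulate_chirp_trials(p), cluster = "A",
                              freqs = seq(2, 100, 2))
    v[["Low Gamma ITPC"]]
  }, numeric(1))
  expect_equal(cor(vals, jitters, method = "spearman"), -1)
})
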