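test_that("filterbank centers are ERB-rate spaced within the sonar band", {
  fb <- fb_default
  expect_equal(length(fb$center_freqs), 20L)
  expect_equal(fb$center_freqs[1], 16000, tolerance = 1e-6)
  expect_equal(fb$center_freqs[20], 70000, tolerance = 1e-6)
  # equal steps on the ERB-rate scale
  r <- erb_rate(fb$center_freqs)
  expect_lt(stats::sd(diff(r)) / mean(diff(r)), 1e-6)
  # Glasberg-Moore bandwidth formula at a spot value
  expect_equal(erb_hz(1000), 24.7 * (4.37 + 1))
  expect_equal(erb_rate_inv(erb_rate(35000)), 35000, tolerance = 1e-6)
})

test_that("cochleagram has the documented shape and maps silence to zero", {
  em <- em_default
  z <- echo_wave(numeric(window_samples()), fs = em$fs)
  cz <- cochleagram(z)
  expect_s3_class(cz, "cochleogram")
  expect_equal(dim(cz$values), c(20L, 7000L))
  expect_true(all(cz$values == 0))
  echo <- synthesize_echo(single_glint_ir(5e-3), em_default)
  expect_true(all(cochleagram(echo)$values >= 0))
  expect_error(cochleagram(em_default), "7000 samples")
})

test_that("cochleagram obeys the compressive power law exactly", {
  echo <- synthesize_echo(single_glint_ir(6e-3), em_default)
  c1 <- cochleagram(echo)
  g <- 3.7
  echo_g <- echo_wave(g * echo$samples, fs = echo$fs)
  cg <- cochleagram(echo_g)
  gamma <- fb_default$compression_exponent
  expect_lt(max(abs(cg$values - g^gamma * c1$values)), 1e-6 * max(cg$values))
})

test_that("a narrowband burst excites the matching channel most", {
  fb <- fb_default
  for (k in c(3L, 10L, 17L)) {
    fc <- fb$center_freqs[k]
    t <- seq(0, 1e-3, by = 1 / fb$fs)
    burst <- numeric(window_samples())
    burst[1000 + seq_along(t)] <- sin(2 * pi * fc * t)
    cc <- cochleagram(echo_wave(burst, fs = fb$fs))
    expect_equal(which.max(rowSums(cc$values)), k)
  }
})

test_that("dechirping aligns channel responses to the glint delay", {
  echo <- synthesize_echo(single_glint_ir(11e-3), em_default)
  raw <- cochleagram(echo)
  dc <- dechirp(raw)
  fs <- fb_default$fs
  peak_t <- function(cc) apply(cc$values, 1L, which.max) / fs
  # before dechirp the peaks straddle ~1 ms of sweep; after, < 0.25 ms
  expect_gt(diff(range(peak_t(raw))), 0.8e-3)
  expect_lt(stats::sd(peak_t(dc)), 0.25e-3)
  expect_lt(abs(mean(peak_t(dc)) - 11e-3), 1e-3)
  expect_error(dechirp(dc), "dechirp")
})

test_that("repeat averaging is exact and suppresses noise variance", {
  echo <- synthesize_echo(single_glint_ir(8e-3), em_default)
  cc <- cochleagram(echo)
  expect_equal(average_repeats(list(cc))$values, cc$values)
  z <- cc; z$values <- matrix(0, 20, 7000)
  m3 <- z; m3$values <- 3 * cc$values
  expect_equal(average_repeats(list(z, m3, z))$values, cc$values)
  # variance of averaged iid noise drops by the number of repeats
  reps <- lapply(1:3, function(k) add_noise(z, noise_model(1, seed = k)))
  v <- stats::var(as.vector(average_repeats(reps)$values))
  expect_lt(abs(v - 1 / 3), 0.05)
  bad <- cc; bad$values <- cc$values[, 1:100]
  expect_error(average_repeats(list(cc, bad)), "shape|dim")
})

test_that("reference-level normalization sets the ensemble maximum to 15", {
  echo <- synthesize_echo(single_glint_ir(11e-3), em_default)
  cc <- dechirp(cochleagram(echo))
  gain <- normalize_reference_level(list(cc), target_max = 15)
  gamma <- fb_default$compression_exponent
  scaled <- sonocode:::scale_cochleogram(cc, gain)
  expect_equal(max(scaled$values), 15, tolerance = 1e-9)
  # the returned gain is a waveform gain: re-synthesizing with it must give
  # the same maximum through the compressive front end
  echo_g <- echo_wave(gain * echo$samples, fs = echo$fs)
  cc_g <- dechirp(cochleagram(echo_g))
  expect_equal(max(cc_g$values), 15, tolerance = 1e-6)
  # power-law inversion spot check
  expect_equal(sonocode:::scale_cochleogram(cc, 2)$values,
               2^gamma * cc$values)
  z <- cc; z$values <- matrix(0, 20, 7000)
  expect_error(normalize_reference_level(list(z)), "zero")
})
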