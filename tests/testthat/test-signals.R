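test_that("emission is a 1 ms downward hyperbolic sweep with unit peak", {
  em <- em_default
  expect_s3_class(em, "echo_wave")
  expect_equal(length(em$samples), 360L)
  expect_equal(max(abs(em$samples)), 1)
  # instantaneous period from zero-crossing spacing must grow monotonically
  # (linear-period sweep, 70 kHz down to 30 kHz)
  s <- em$samples
  i <- which(s[-length(s)] < 0 & s[-1] >= 0)
  # sub-sample crossing times by linear interpolation
  tc <- (i - s[i] / (s[i + 1] - s[i])) / em$fs
  periods <- diff(tc)
  expect_true(all(diff(periods) >= -1e-9))
  f_start <- 1 / periods[1]
  f_end <- 1 / periods[length(periods)]
  expect_lt(abs(f_start - 70000) / 70000, 0.1)
  expect_lt(abs(f_end - 30000) / 30000, 0.1)
})

test_that("emission construction rejects an unrepresentable sweep", {
  expect_error(make_emission(emission_spec(), fs = 100000),
               "sample rate")
})

test_that("single-glint impulse responses encode delay and level", {
  ir <- single_glint_ir(11e-3)
  expect_equal(ir$delays, 11e-3)
  expect_equal(ir$amplitudes, 1)
  ir6 <- single_glint_ir(11e-3, gain_db = -6)
  expect_equal(ir6$amplitudes, db_to_lin(-6))
  expect_lt(abs(ir6$amplitudes - 0.5012), 5e-4)
  # outside the analysis window
  expect_error(single_glint_ir(25e-3), "window")
  expect_error(impulse_response(-1e-3, 1), "delays must lie")
})

test_that("two-glint echoes carry notches at odd multiples of 1/(2 tau)", {
  f0 <- notch_frequencies(10e-6, m_max = 2L)
  expect_equal(f0, c(50000, 150000, 250000))
  expect_equal(tau_for_notch(50000), 10e-6)
  expect_equal(tau_for_notch(notch_frequencies(7.77e-6, 0L)), 7.77e-6)
  # spectral oracle: synthesized two-glint echo has its in-band magnitude
  # minimum at 1/(2 tau)
  em <- em_default
  echo <- synthesize_echo(two_glint_ir(two_glint_spec(10e-6)), em)
  n <- length(echo$samples)
  nfft <- 2^16
  mag <- abs(fft(c(echo$samples, numeric(nfft - n))))
  fr <- (seq_len(nfft) - 1) * echo$fs / nfft
  band <- fr >= 35000 & fr <= 65000
  f_min <- fr[band][which.min(mag[band])]
  expect_lt(abs(f_min - 50000), 500)
})

test_that("two-glint spectral magnitude matches the interference formula", {
  # |X(f)| = |E(f)| * |1 + a exp(-i 2 pi f tau)| for a two-glint target
  em <- em_default
  tau <- 30e-6; a <- 0.7
  echo <- synthesize_echo(two_glint_ir(two_glint_spec(tau, a = a)), em)
  nfft <- 2^15
  pad <- function(x) c(x, numeric(nfft - length(x)))
  base <- synthesize_echo(single_glint_ir(11e-3), em)
  fr <- (seq_len(nfft) - 1) * em$fs / nfft
  pred <- abs(fft(pad(base$samples))) * abs(1 + a * exp(-2i * pi * fr * tau))
  got <- abs(fft(pad(echo$samples)))
  band <- fr >= 32000 & fr <= 68000
  expect_lt(max(abs(got[band] - pred[band])) / max(pred[band]), 0.01)
})

test_that("random impulse responses are uniform over the span and seeded", {
  ir1 <- random_ir(12L, span = 1.86e-3, seed = 9L)
  ir2 <- random_ir(12L, span = 1.86e-3, seed = 9L)
  expect_identical(ir1, ir2)
  expect_equal(length(ir1$delays), 12L)
  expect_true(all(diff(ir1$delays) >= 0))
  expect_true(all(ir1$delays >= 11e-3 & ir1$delays <= 11e-3 + 1.86e-3))
  # distribution oracle: pooled normalized delays ~ U(0, 1)
  d <- unlist(lapply(1:840, function(k)
    random_ir(12L, span = 1.86e-3, seed = 1000L + k)$delays))
  u <- (d - 11e-3) / 1.86e-3
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("target rescaling follows the physical size law", {
  ir <- random_ir(12L, span = 1.86e-3, seed = 4L)
  expect_equal(scale_ir(ir, 1), ir)
  ir2 <- scale_ir(ir, 1.5)
  # delays stretch about the first glint; amplitudes scale with area (s^2)
  expect_equal(ir2$delays - ir2$delays[1], 1.5 * (ir$delays - ir$delays[1]))
  expect_equal(ir2$delays[1], ir$delays[1])
  expect_equal(ir2$amplitudes, 1.5^2 * ir$amplitudes)
  # round trip
  back <- scale_ir(ir2, 1 / 1.5)
  expect_equal(back$delays, ir$delays, tolerance = 1e-12)
  expect_equal(back$amplitudes, ir$amplitudes, tolerance = 1e-12)
  expect_error(scale_ir(ir, 20), "window")
})

test_that("echo synthesis is an exact delay-and-sum of the emission", {
  em <- em_default
  d <- 400L  # integer sample delay
  echo <- synthesize_echo(single_glint_ir(d / em$fs), em)
  expect_equal(length(echo$samples), window_samples())
  expected <- numeric(window_samples())
  expected[d + seq_along(em$samples)] <- em$samples
  expect_lt(max(abs(echo$samples - expected)), 1e-6)
  # superposition: two glints = sum of the singles
  ir_a <- single_glint_ir(3e-3)
  ir_b <- single_glint_ir(5e-3, gain_db = -6)
  both <- impulse_response(c(3e-3, 5e-3), c(1, db_to_lin(-6)))
  e_sum <- synthesize_echo(ir_a, em)$samples + synthesize_echo(ir_b, em)$samples
  expect_lt(max(abs(synthesize_echo(both, em)$samples - e_sum)), 1e-9)
})

test_that("level roving spans the configured range and is seeded", {
  em <- em_default
  ir <- single_glint_ir(11e-3)
  g <- vapply(1:2000, function(k) {
    e <- synthesize_echo(ir, em, rove_db = 30, seed = k)
    max(abs(e$samples))
  }, numeric(1))
  r <- lin_to_db(max(g) / min(g))
  expect_gt(r, 28)
  expect_lte(r, 30 + 1e-6)
  e1 <- synthesize_echo(ir, em, rove_db = 30, seed = 7L)
  e2 <- synthesize_echo(ir, em, rove_db = 30, seed = 7L)
  expect_identical(e1, e2)
})

test_that("waveform and impulse-response files round-trip", {
  em <- em_default
  p <- tempfile(fileext = ".wav")
  write_wav(em, p)
  back <- read_wav(p)
  expect_equal(back$fs, em$fs)
  expect_equal(back$samples, em$samples, tolerance = 1e-6)  # float32
  ir <- random_ir(5L, span = 1e-3, seed = 2L)
  q <- tempfile(fileext = ".csv")
  write_ir_csv(ir, q)
  ir_back <- read_ir_csv(q)
  expect_equal(ir_back$delays, ir$delays, tolerance = 1e-12)
  expect_equal(ir_back$amplitudes, ir$amplitudes, tolerance = 1e-12)
  unlink(c(p, q))
})

test_that("toy HRTF places an elevation-dependent notch and is otherwise flat", {
  h <- make_toy_hrtf()
  em <- em_default
  echo <- synthesize_echo(single_glint_ir(5e-3), em)
  # elevation 0: notch at 50 kHz; +10 deg: 55 kHz (0.5 kHz per degree)
  notch_at <- function(elev) {
    e <- apply_hrtf(echo, elev, h)
    nfft <- 2^15
    mag <- abs(fft(c(e$samples, numeric(nfft - length(e$samples)))))
    fr <- (seq_len(nfft) - 1) * e$fs / nfft
    band <- fr >= 36000 & fr <= 64000
    fr[band][which.min(mag[band])]
  }
  expect_lt(abs(notch_at(0) - 50000), 1000)
  expect_lt(abs(notch_at(10) - 55000), 1000)
  expect_lt(abs(notch_at(-5) - 47500), 1000)
  # the full notch family must stay inside the emission band
  expect_error(make_toy_hrtf(notch_slope = 2000), "band")
  # zero depth = identity (group delay compensated)
  h0 <- make_toy_hrtf(depth_db = 0)
  e0 <- apply_hrtf(echo, 13, h0)
  expect_lt(max(abs(e0$samples - echo$samples)), 1e-4)
  expect_error(apply_hrtf(echo, 45, h), "elevation")
})
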