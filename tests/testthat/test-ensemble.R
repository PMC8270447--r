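test_that("frequency-dependent absorption follows the configured power law", {
  m <- propagation_model()
  expect_equal(sonocode:::absorption_db_per_m(m, 35000), 1.0)
  expect_equal(sonocode:::absorption_db_per_m(m, 70000), 2^1.6)
  m2 <- propagation_model(alpha0_db_per_m = 2.0)
  expect_equal(sonocode:::absorption_db_per_m(m2, 35000), 2.0)
  expect_error(propagation_model(spreading_exponent = 0), "spreading")
})

test_that("propagation attenuates high frequencies more with range", {
  em <- em_default
  echo <- synthesize_echo(single_glint_ir(2e-3), em)
  m0 <- propagation_model(alpha0_db_per_m = 0)
  same <- propagate(echo, range = 1.5, model = m0)
  # zero absorption: waveform unchanged (spreading lives in IR amplitudes)
  expect_equal(same$samples, echo$samples, tolerance = 1e-9)
  att <- propagate(echo, range = 3, model = propagation_model())
  nfft <- 2^14
  spec_of <- function(e) abs(fft(c(e$samples, numeric(nfft - length(e$samples)))))
  fr <- (seq_len(nfft) - 1) * em$fs / nfft
  ratio <- spec_of(att) / pmax(spec_of(echo), 1e-12)
  b35 <- which.min(abs(fr - 35000)); b65 <- which.min(abs(fr - 65000))
  # two-way 6 m path at 1 dB/m (35 kHz): about -6 dB there, more at 65 kHz
  expect_lt(abs(lin_to_db(ratio[b35]) + 6), 1)
  expect_lt(lin_to_db(ratio[b65]), lin_to_db(ratio[b35]) - 3)
})

test_that("location scenes have the configured statistics and determinism", {
  l1 <- location_spec("L1", "sparse_glints", seed = 31L)
  l2 <- location_spec("L1", "sparse_glints", seed = 31L)
  expect_identical(l1, l2)
  expect_true(all(l1$scene$range >= l1$range[1] & l1$scene$range <= l1$range[2]))
  # dense regime: Poisson glint count with the configured mean (within 5 %)
  counts <- vapply(1:2000, function(k)
    nrow(location_spec("d", "dense_stochastic", seed = 40000L + k)$scene),
    numeric(1))
  expect_lt(abs(mean(counts) - 25) / 25, 0.05)
  expect_gt(stats::var(counts), 10)   # genuinely dispersed, not fixed
  expect_error(location_spec("x", "sparse_glints", range = c(2, 1)), "range")
})

test_that("an impulse response realizes reflectivity over squared range", {
  loc <- location_spec("L2", "sparse_glints", pose_jitter = 0,
                       glint_jitter = 0, reflect_jitter = 0, seed = 33L)
  ir <- sample_location_ir(loc, seed = 34L)
  sc <- loc$scene
  ord <- order(sc$range)
  expect_equal(ir$amplitudes, (sc$reflectivity / sc$range^2)[ord],
               tolerance = 1e-12)
  expect_equal(ir$delays,
               sort(2 * sc$range / propagation_model()$speed_of_sound),
               tolerance = 1e-12)
  # jitter-free: poses coincide; with jitter: they differ
  ir2 <- sample_location_ir(loc, seed = 99L)
  expect_equal(ir$delays, ir2$delays)
  locj <- location_spec("L3", "sparse_glints", seed = 33L)
  j1 <- sample_location_ir(locj, seed = 1L)
  j2 <- sample_location_ir(locj, seed = 2L)
  expect_false(isTRUE(all.equal(j1$delays, j2$delays)))
})

test_that("the default campaign has 21 labeled locations with sibling pairs", {
  locs <- default_location_specs(seed = 35L)
  expect_equal(length(locs), 21L)
  regimes <- vapply(locs, `[[`, "", "regime")
  expect_equal(sum(regimes == "sparse_glints"), 11L)
  expect_equal(sum(regimes == "dense_stochastic"), 10L)
  sib_ix <- which(!vapply(lapply(locs, `[[`, "sibling_of"), is.null, TRUE))
  expect_equal(length(sib_ix), 3L)
  # a sibling's scene is a perturbation of its partner's, not a redraw:
  # same glint count, near-identical ranges
  s <- sib_ix[1]
  p <- which(vapply(locs, `[[`, "", "id") == locs[[s]]$sibling_of)
  expect_equal(nrow(locs[[s]]$scene), nrow(locs[[p]]$scene))
  expect_gt(stats::cor(locs[[s]]$scene$range, locs[[p]]$scene$range), 0.99)
})

test_that("dataset generation is seeded, labeled and repeat-structured", {
  locs <- default_location_specs(n_locations = 4L, n_indoor = 2L,
                                 n_sibling_pairs = 1L, seed = 36L)
  d1 <- generate_dataset(locations = locs, poses_per_location = c(3L, 5L),
                         seed = 37L)
  d2 <- generate_dataset(locations = locs, poses_per_location = c(3L, 5L),
                         seed = 37L)
  expect_identical(d1, d2)
  expect_equal(nlevels(d1$location), 4L)
  expect_equal(length(d1$echoes), 3L * length(unique(d1$pose)))
  per_loc <- table(d1$location) / 3L
  expect_true(all(per_loc >= 3L & per_loc <= 5L))
  # repeats of one pose differ only by measurement noise at ~30 dB SNR
  ix <- which(d1$pose == d1$pose[1])
  expect_equal(length(ix), 3L)
  e1 <- d1$echoes[[ix[1]]]$samples; e2 <- d1$echoes[[ix[2]]]$samples
  expect_false(identical(e1, e2))
  snr_db <- lin_to_db(sqrt(sum(((e1 + e2) / 2)^2) / sum(((e1 - e2) / 2)^2)))
  expect_gt(snr_db, 24)
  expect_lt(snr_db, 36)
  # averaged cochleograms: one per pose, labels follow locations
  ens <- ensemble_cochleograms(d1)
  expect_equal(length(ens$cochs), length(unique(d1$pose)))
  expect_equal(length(ens$labels), length(ens$cochs))
  expect_true(all(table(ens$labels) >= 3L))
})

test_that("the paper-scale preset reaches the published echo count", {
  d <- generate_dataset(preset = "paper", seed = 38L)
  expect_equal(length(d$echoes), 1014L)
  expect_equal(length(unique(d$pose)), 338L)
  regimes <- stats::setNames(vapply(d$locations, `[[`, "", "regime"),
                             vapply(d$locations, `[[`, "", "id"))
  indoor <- sum(regimes[as.character(d$location)] == "sparse_glints")
  expect_gte(indoor, 495L)
  expect_lte(indoor, 510L)
})
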