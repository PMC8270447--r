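test_that("threshold interpolation follows hand-checkable arithmetic", {
  th <- threshold_from_curve(c(0, 10), c(50, 100), criterion = 75)
  expect_equal(th$threshold, 5)
  expect_equal(th$status, "interpolated")
  # hardest condition already above criterion: report the edge
  th2 <- threshold_from_curve(c(2, 4, 8), c(90, 95, 99))
  expect_equal(th2$threshold, 2)
  expect_equal(th2$status, "at_edge")
  # never crossing: beyond range
  th3 <- threshold_from_curve(c(2, 4, 8), c(50, 55, 60))
  expect_equal(th3$threshold, Inf)
  expect_equal(th3$status, "beyond_range")
  expect_error(threshold_from_curve(1:3, 1:2), "equal-length")
  # folding a symmetric curve averages the two sides
  curve <- data.frame(condition = c(-2, -1, 1, 2),
                      pct_correct = c(80, 60, 70, 90))
  fc <- sonocode:::fold_curve(curve)
  expect_equal(fc$x, c(65, 85))
  expect_equal(fc$difficulty, c(1, 2))
})

test_that("experiment configurations carry the documented stimulus grids", {
  cfg1 <- experiment_config(1)
  expect_equal(length(cfg1$offsets_us), 10L)
  expect_equal(cfg1$rove_db, 30)
  st1 <- sonocode:::experiment_stimuli(cfg1)$stimuli
  expect_equal(length(st1), 20L)  # rewarded + unrewarded per offset
  cfg2 <- experiment_config(2)
  st2 <- sonocode:::experiment_stimuli(cfg2)$stimuli
  expect_equal(length(unique(vapply(st2, `[[`, 0, "condition"))), 28L)
  expect_equal(cfg2$rove_mode, "per_glint")
  cfg3 <- experiment_config(3)
  expect_equal(length(cfg3$scales), 15L)
  expect_equal(range(cfg3$scales), c(0.65, 1.5))
  cfg4 <- experiment_config(4)
  expect_equal(length(cfg4$elevations), 40L)
  expect_false(0 %in% cfg4$elevations)
  expect_error(experiment_config(5), "1, 2, 3 or 4")
})

test_that("reference gain and internal noise calibrate coherently", {
  tn <- tiny_noise()
  expect_gt(tn$ref_gain, 0)
  expect_s3_class(tn$noise, "noise_model")
  # the calibrated sigma reproduces ~70 % correct on the 5 dB step
  em <- em_default
  e <- synthesize_echo(single_glint_ir(11e-3), em)
  e$samples <- e$samples * tn$ref_gain
  s_ref <- dechirp(cochleagram(e))
  expect_equal(max(s_ref$values), 15, tolerance = 1e-6)
  s_plus <- s_ref
  s_plus$values <- db_to_lin(5)^fb_default$compression_exponent * s_ref$values
  p <- discrimination_probability(s_ref, s_plus, tn$noise$sigma,
                                  n_mc = 50000L, seed = 12L)
  expect_lt(abs(p - 0.70), 0.02)
})

test_that("trials have the documented structure and decode to the stimulus", {
  w <- tiny_world()
  cfg <- experiment_config(1, n_train = 40L, n_test = 20L, rove_db = 0,
                           ref_gain = tiny_noise()$ref_gain)
  trials <- build_trials(cfg, w$basis, noise_model(0), seed = 5L)
  expect_s3_class(trials, "trial_set")
  expect_equal(ncol(trials$codes), 25L)
  expect_equal(sum(trials$role == "train"), 20L * 20L)
  expect_equal(sum(trials$role == "test"), 10L * 20L)
  expect_equal(sort(unique(trials$label)), c(0L, 1L))
  expect_true(all(sort(unique(trials$condition)) == cfg$offsets_us))
  # a rewarded trial decodes to a cochleogram whose temporal energy peaks
  # at the rewarded 11 ms delay
  ix <- which(trials$label == 1L)[1]
  recon <- decode(trials$codes[ix, ], w$basis)
  expect_s3_class(recon, "cochleogram")
  expect_true(isTRUE(recon$reconstructed))
  t_peak <- which.max(colSums(pmax(recon$values, 0))) / fb_default$fs
  expect_lt(abs(t_peak - 11e-3), 2e-3)
})

test_that("code-space noise equals encoded cochleogram noise in law", {
  w <- tiny_world()
  sigma <- 5
  um <- unmixing_matrix(w$basis)
  target <- sigma^2 * tcrossprod(um)
  # literal path: encode pure noise fields and compare second moments
  set.seed(77)
  n <- 400L
  draws <- vapply(seq_len(n), function(i) {
    as.numeric(um %*% rnorm(140000L, 0, sigma))
  }, numeric(25L))
  emp <- tcrossprod(draws) / n
  expect_gt(stats::cor(as.vector(emp), as.vector(target)), 0.95)
  expect_lt(max(abs(diag(emp) / diag(target) - 1)), 0.35)
  # and the packaged fast path is exactly seeded/reproducible
  cfg <- experiment_config(1, n_train = 10L, n_test = 10L,
                           ref_gain = tiny_noise()$ref_gain)
  t1 <- build_trials(cfg, w$basis, noise_model(sigma), seed = 3L)
  t2 <- build_trials(cfg, w$basis, noise_model(sigma), seed = 3L)
  expect_identical(t1$codes, t2$codes)
})

test_that("a noiseless scale-discrimination run trains and generalizes", {
  w <- tiny_world()
  cfg <- experiment_config(3, n_train = 60L, n_test = 30L,
                           ref_gain = tiny_noise()$ref_gain)
  res <- run_experiment(cfg, w$basis, noise_model(0),
                        net_spec = discriminator_spec(seed = 8L), seed = 9L)
  expect_equal(res$experiment, 3L)
  expect_s3_class(res$curve, "psychometric_curve")
  expect_s3_class(res$curve_generalization, "psychometric_curve")
  expect_equal(nrow(res$curve), 15L)
  # protocol 1 is trained at scale 1 only: near-perfect there
  at1 <- res$curve$pct_correct[which.min(abs(res$curve$condition - 1))]
  expect_gte(at1, 90)
  # protocol 2 (trained at 0.65, 1, 1.5) solves every scale without noise
  expect_gte(min(res$curve_generalization$pct_correct), 90)
})
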