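# Simulated 2AFC psychophysics. Four classic experiments are rebuilt as
# phantom-target stimulus generators feeding the full pipeline: impulse
# response -> echo synthesis (with optional amplitude roving) -> cochleogram
# -> dechirp -> internal noise -> 25-D code -> discriminator network.
#
# All phantom stimuli are presented at a fixed reference level chosen so
# the rewarded single-glint echo's cochleogram hits the ensemble ceiling
# (15 m.u. by default); the internal-noise sigma is calibrated at that same
# reference, which makes thresholds invariant to the choice.

#' Reference waveform gain for phantom stimuli
#'
#' The gain that brings a unit-amplitude single-glint echo's cochleogram
#' maximum to `target_max` model units, anchoring all phantom stimuli to
#' the normalized ensemble scale.
#'
#' @param fb_spec A [filterbank_spec()].
#' @param em_spec An [emission_spec()].
#' @param delay Glint delay of the anchor stimulus in seconds.
#' @param target_max Cochleogram ceiling in model units.
#' @return Scalar waveform gain.
#' @export
calibrate_reference_gain <- function(fb_spec = filterbank_spec(),
                                     em_spec = emission_spec(),
                                     delay = 11e-3, target_max = 15) {
  em <- make_emission(em_spec, fb_spec$fs)
  echo <- synthesize_echo(single_glint_ir(delay), em)
  cc <- dechirp(cochleagram(echo, fb_spec), em_spec)
  normalize_reference_level(list(cc), target_max)
}

#' Calibrate internal noise at the intensity JND
#'
#' Builds the reference single-glint cochleogram and its `step_db`-louder
#' twin at the phantom reference level, then calls [calibrate_sigma()].
#'
#' @inheritParams calibrate_reference_gain
#' @param ref_gain Reference waveform gain (from
#'   [calibrate_reference_gain()]).
#' @param step_db Intensity step in dB (the JND; default 5).
#' @param target_p Probability correct at the JND (default 0.70).
#' @param n_mc,seed Monte-Carlo settings for [calibrate_sigma()].
#' @return A [noise_model()] with the calibrated sigma.
#' @export
calibrate_internal_noise <- function(ref_gain, fb_spec = filterbank_spec(),
                                     em_spec = emission_spec(), delay = 11e-3,
                                     step_db = 5, target_p = 0.70,
                                     n_mc = 20000L, seed = 1L) {
  em <- make_emission(em_spec, fb_spec$fs)
  mk <- function(gain) {
    e <- synthesize_echo(single_glint_ir(delay), em)
    e$samples <- e$samples * gain
    dechirp(cochleagram(e, fb_spec), em_spec)
  }
  s_ref <- mk(ref_gain)
  s_plus <- mk(ref_gain * db_to_lin(step_db))
  noise_model(calibrate_sigma(s_ref, s_plus, target_p = target_p,
                              n_mc = n_mc, seed = seed))
}

#' Configuration of a simulated behavioral experiment
#'
#' Defaults per experiment:
#' \describe{
#'   \item{1 (echo delay)}{rewarded single glint at 11 ms; unrewarded
#'     shifted backward by 5-1000 us (grid extends below the classic
#'     50-1000 us range so the 75 % crossing is measurable); 30 dB joint
#'     amplitude roving.}
#'   \item{2 (spectral notch)}{two glints, rewarded inter-glint delay 10 us
#'     (first notch at 50 kHz); unrewarded delays place the first notch at
#'     16-70 kHz in 2 kHz steps; leading glint 6 dB below the trailing one;
#'     30 dB roving, independently per glint.}
#'   \item{3 (reflector scaling)}{two fixed random 12-glint impulse
#'     responses over 1.86 ms; 15 scale factors in 0.65-1.5 (amplitudes
#'     scale as s^2, delays as s); trained at scale 1 (protocol 1) or at
#'     scales 0.65, 1, 1.5 (protocol 2).}
#'   \item{4 (elevation)}{single glint filtered by an elevation-notch HRTF
#'     at -20..20 degrees (0 excluded); label is the sign of elevation.}
#' }
#'
#' @param experiment Experiment id, 1-4.
#' @param n_train,n_test Trials per condition for training and testing.
#' @param rove_db,rove_mode Amplitude roving range and mode (see
#'   [synthesize_echo()]); experiment-specific defaults.
#' @param fb_spec,em_spec Peripheral model and emission specifications.
#' @param ref_gain Reference waveform gain; `NULL` computes it via
#'   [calibrate_reference_gain()] when the experiment is run.
#' @param ... Experiment-specific overrides: `rewarded_delay`, `offsets_us`
#'   (1); `base_delay`, `rewarded_notch`, `notch_grid`, `leading_gain_db`
#'   (2); `n_glints`, `span`, `scales`, `train_scales`, `ir_seed` (3);
#'   `delay`, `elevations`, `hrtf` (4).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, n_train = 500L, n_test = 200L,
                              rove_db = NULL, rove_mode = NULL,
                              fb_spec = filterbank_spec(),
                              em_spec = emission_spec(), ref_gain = NULL,
                              ...) {
  if (!experiment %in% 1:4) stop("`experiment` must be 1, 2, 3 or 4")
  extra <- list(...)
  base <- switch(as.character(experiment),
    "1" = list(rewarded_delay = 11e-3,
               offsets_us = c(5, 10, 15, 20, 30, 50, 100, 200, 500, 1000),
               rove_db = 30, rove_mode = "joint"),
    "2" = list(base_delay = 11e-3, rewarded_notch = 50000,
               notch_grid = seq(16000, 70000, by = 2000),
               leading_gain_db = -6, rove_db = 30, rove_mode = "per_glint"),
    "3" = list(base_delay = 11e-3, n_glints = 12L, span = 1.86e-3,
               # 15 scale conditions spanning 0.65-1.5 and containing the
               # trained scale 1 exactly
               scales = c(seq(0.65, 1, length.out = 8),
                          seq(1, 1.5, length.out = 8)[-1]),
               train_scales = 1, ir_seed = 42L, rove_db = 0,
               rove_mode = "joint"),
    "4" = list(delay = 11e-3, elevations = setdiff(seq(-20, 20, by = 1), 0),
               hrtf = NULL, rove_db = 0, rove_mode = "joint"))
  cfg <- utils::modifyList(base, extra)
  if (!is.null(rove_db)) cfg$rove_db <- rove_db
  if (!is.null(rove_mode)) cfg$rove_mode <- rove_mode
  cfg$experiment <- as.integer(experiment)
  cfg$n_train <- as.integer(n_train)
  cfg$n_test <- as.integer(n_test)
  cfg$fb_spec <- fb_spec
  cfg$em_spec <- em_spec
  cfg$ref_gain <- ref_gain
  structure(cfg, class = "experiment_config")
}

# small reusable pieces of the encoding map for fast trial generation
#' @keywords internal
encoder_maps <- function(basis, sigma) {
  um <- unmixing_matrix(basis)
  um_mu <- as.numeric(um %*% basis$mean)
  M <- tcrossprod(um)                  # covariance shape of encoded noise
  R <- chol(M + diag(1e-12 * max(diag(M)), nrow(M)))
  list(um = um, um_mu = um_mu, noise_chol = R, sigma = sigma)
}

# stimulus table for an experiment: one row per distinct clean stimulus
# (ir or prepared waveform), with condition value and label
#' @keywords internal
experiment_stimuli <- function(cfg) {
  em <- make_emission(cfg$em_spec, cfg$fb_spec$fs)
  out <- list()
  add <- function(condition, label, ir = NULL, wave = NULL)
    out[[length(out) + 1L]] <<- list(condition = condition, label = label,
                                     ir = ir, wave = wave)
  if (cfg$experiment == 1L) {
    for (off in cfg$offsets_us) {
      add(off, 1L, ir = single_glint_ir(cfg$rewarded_delay))
      add(off, 0L, ir = single_glint_ir(cfg$rewarded_delay + off * 1e-6))
    }
  } else if (cfg$experiment == 2L) {
    tau_r <- tau_for_notch(cfg$rewarded_notch)
    for (fn in cfg$notch_grid) {
      add(fn, 1L, ir = two_glint_ir(two_glint_spec(tau_r, a = 1,
                                                   cfg$base_delay),
                                    leading_gain_db = cfg$leading_gain_db))
      add(fn, 0L, ir = two_glint_ir(two_glint_spec(tau_for_notch(fn), a = 1,
                                                   cfg$base_delay),
                                    leading_gain_db = cfg$leading_gain_db))
    }
  } else if (cfg$experiment == 3L) {
    ir_a <- random_ir(cfg$n_glints, cfg$span, cfg$base_delay,
                      seed = child_seed(cfg$ir_seed, 1L))
    ir_b <- random_ir(cfg$n_glints, cfg$span, cfg$base_delay,
                      seed = child_seed(cfg$ir_seed, 2L))
    for (s in sort(unique(c(cfg$scales, cfg$train_scales)))) {
      add(s, 1L, ir = scale_ir(ir_a, s))
      add(s, 0L, ir = scale_ir(ir_b, s))
    }
  } else {
    hrtf <- if (is.null(cfg$hrtf)) make_toy_hrtf(fs = cfg$fb_spec$fs)
            else cfg$hrtf
    base <- synthesize_echo(single_glint_ir(cfg$delay), em)
    for (el in cfg$elevations)
      add(el, as.integer(el > 0), wave = apply_hrtf(base, el, hrtf))
  }
  list(stimuli = out, emission = em)
}

# clean dechirped cochleogram of one stimulus at the reference level
#' @keywords internal
stimulus_cochleogram <- function(st, em, cfg) {
  w <- if (!is.null(st$wave)) st$wave
       else synthesize_echo(st$ir, em)
  w$samples <- w$samples * cfg$ref_gain
  dechirp(cochleagram(w, cfg$fb_spec), cfg$em_spec)
}

#' Build labeled, encoded trials for an experiment
#'
#' Runs the stimulus pipeline for every trial: phantom impulse response,
#' echo synthesis with amplitude roving, cochleogram, dechirping, internal
#' noise, 25-D encoding. Rewarded trials carry label 1.
#'
#' Internal noise is by default sampled directly in code space from its
#' exact induced distribution `N(0, sigma^2 Um Um')` (`Um` the linear
#' unmixing map) — identical in law to adding the noise field to the
#' cochleogram and encoding, at a fraction of the cost; set
#' `noise_space = "cochleogram"` for the literal path. Joint roving is
#' applied through the model's exact amplitude-power law; per-glint roving
#' synthesizes each trial's waveform individually.
#'
#' @param cfg An [experiment_config()] (with `ref_gain` set).
#' @param basis An `encoding_basis`.
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @param noise_space `"code"` (exact, fast) or `"cochleogram"` (literal).
#' @return An object of class `trial_set`: `$codes` (matrix), `$label`,
#'   `$condition`, `$role` (`"train"`/`"test"`).
#' @export
build_trials <- function(cfg, basis, noise, seed = 1L,
                         noise_space = c("code", "cochleogram")) {
  if (!inherits(cfg, "experiment_config")) stop("`cfg` must be an experiment_config")
  if (!inherits(basis, "encoding_basis")) stop("`basis` must be an encoding_basis")
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  noise_space <- match.arg(noise_space)
  if (is.null(cfg$ref_gain))
    cfg$ref_gain <- calibrate_reference_gain(cfg$fb_spec, cfg$em_spec)
  es <- experiment_stimuli(cfg)
  gamma <- cfg$fb_spec$compression_exponent
  maps <- encoder_maps(basis, noise$sigma)
  k <- basis$n_components

  # which conditions receive train / test trials
  train_cond <- if (cfg$experiment == 3L) cfg$train_scales
                else unique(vapply(es$stimuli, `[[`, numeric(1), "condition"))
  per_glint <- cfg$rove_db > 0 && cfg$rove_mode == "per_glint"

  codes <- list(); label <- integer(); condition <- numeric(); role <- character()
  with_rng_seed(seed, {
    for (st in es$stimuli) {
      n_tr <- if (st$condition %in% train_cond) ceiling(cfg$n_train / 2) else 0L
      n_te <- ceiling(cfg$n_test / 2)
      n <- n_tr + n_te
      if (n == 0L) next
      if (!per_glint && noise_space == "code") {
        cc <- stimulus_cochleogram(st, es$emission, cfg)
        u_s <- as.numeric(maps$um %*% as.vector(cc$values))
        g <- if (cfg$rove_db > 0)
          db_to_lin(stats::runif(n, -cfg$rove_db / 2, cfg$rove_db / 2))
          else rep(1, n)
        mat <- outer(g^gamma, u_s) - rep(maps$um_mu, each = n)
        if (noise$sigma > 0)
          mat <- mat + noise$sigma *
            (matrix(stats::rnorm(n * k), n, k) %*% maps$noise_chol)
      } else {
        mat <- matrix(0, n, k)
        for (j in seq_len(n)) {
          w <- if (!is.null(st$wave)) {
            ww <- st$wave
            if (cfg$rove_db > 0)
              ww$samples <- ww$samples *
                db_to_lin(stats::runif(1, -cfg$rove_db / 2, cfg$rove_db / 2))
            ww
          } else synthesize_echo(st$ir, es$emission, rove_db = cfg$rove_db,
                                 rove_mode = cfg$rove_mode)
          w$samples <- w$samples * cfg$ref_gain
          cc <- dechirp(cochleagram(w, cfg$fb_spec), cfg$em_spec)
          if (noise_space == "cochleogram" && noise$sigma > 0)
            cc <- add_noise(cc, noise_model(noise$sigma))
          code <- encode(cc, basis)[1L, ]
          if (noise_space == "code" && noise$sigma > 0)
            code <- code + noise$sigma *
              as.numeric(stats::rnorm(k) %*% maps$noise_chol)
          mat[j, ] <- code
        }
      }
      codes[[length(codes) + 1L]] <- mat
      label <- c(label, rep(st$label, n))
      condition <- c(condition, rep(st$condition, n))
      role <- c(role, rep(c("train", "test"), c(n_tr, n_te)))
    }
  })
  structure(list(codes = do.call(rbind, codes), label = label,
                 condition = condition, role = role, cfg = cfg),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> experiment %d: %d trials (%d train / %d test), %d conditions\n",
              x$cfg$experiment, length(x$label), sum(x$role == "train"),
              sum(x$role == "test"), length(unique(x$condition))))
  invisible(x)
}

#' Train the 2AFC discriminator on a trial set
#'
#' @param trials A `trial_set` from [build_trials()].
#' @param spec An [mlp_spec()]; default [discriminator_spec()].
#' @return A trained `mlp`.
#' @export
train_discriminator <- function(trials, spec = discriminator_spec()) {
  if (!inherits(trials, "trial_set")) stop("`trials` must be a trial_set")
  tr <- trials$role == "train"
  if (length(unique(trials$label[tr])) < 2L)
    stop("training trials contain a single class")
  mlp_train(trials$codes[tr, , drop = FALSE], trials$label[tr], spec)
}

#' Psychometric curve of a trained discriminator
#'
#' Percent correct per condition on the held-out test trials (output >= 0.5
#' is read as "rewarded").
#'
#' @param model A trained `mlp`.
#' @param trials A `trial_set`.
#' @param criterion Percent-correct criterion for thresholds (default 75).
#' @return An object of class `psychometric_curve`: a data frame of
#'   `condition`, `pct_correct`, `n`, with the criterion attached.
#' @export
psychometric <- function(model, trials, criterion = 75) {
  te <- trials$role == "test"
  if (length(unique(trials$condition[te])) < 2L)
    stop("need at least two test conditions")
  pred <- as.integer(mlp_predict(model, trials$codes[te, , drop = FALSE]) >= 0.5)
  ok <- pred == trials$label[te]
  agg <- stats::aggregate(ok, by = list(condition = trials$condition[te]),
                          FUN = function(v) c(mean(v), length(v)))
  curve <- data.frame(condition = agg$condition,
                      pct_correct = 100 * agg$x[, 1], n = agg$x[, 2])
  curve <- curve[order(curve$condition), ]
  rownames(curve) <- NULL
  structure(curve, class = c("psychometric_curve", "data.frame"),
            criterion = criterion)
}

#' Threshold of a psychometric curve at a criterion
#'
#' Conditions must be supplied ordered from hardest to easiest. The
#' threshold is the linearly interpolated difficulty at which percent
#' correct first crosses the criterion coming from the hard side. If the
#' hardest tested condition is already at or above criterion the threshold
#' is reported at that edge; if the curve never reaches the criterion the
#' threshold is `Inf` ("beyond range").
#'
#' @param difficulty Condition values, hardest first.
#' @param pct_correct Percent correct per condition.
#' @param criterion Criterion in percent (default 75).
#' @return A list with `threshold` (difficulty units) and `status`
#'   (`"interpolated"`, `"at_edge"` or `"beyond_range"`).
#' @export
threshold_from_curve <- function(difficulty, pct_correct, criterion = 75) {
  if (length(difficulty) != length(pct_correct) || length(difficulty) < 2L)
    stop("`difficulty` and `pct_correct` must be equal-length (>= 2)")
  if (pct_correct[1] >= criterion)
    return(list(threshold = difficulty[1], status = "at_edge"))
  for (i in 2:length(difficulty)) {
    if (pct_correct[i] >= criterion) {
      th <- difficulty[i - 1] + (criterion - pct_correct[i - 1]) *
        (difficulty[i] - difficulty[i - 1]) /
        (pct_correct[i] - pct_correct[i - 1])
      return(list(threshold = th, status = "interpolated"))
    }
  }
  list(threshold = Inf, status = "beyond_range")
}

# fold a two-sided curve (e.g. elevations) onto |condition| and average
#' @keywords internal
fold_curve <- function(curve, center = 0) {
  d <- abs(curve$condition - center)
  agg <- stats::aggregate(curve$pct_correct, by = list(difficulty = d), mean)
  agg[order(agg$difficulty), ]
}

#' Run a complete simulated behavioral experiment
#'
#' Orchestrates trial building, discriminator training and psychometric
#' evaluation. Experiment 3 runs both protocols: a network trained at scale
#' 1 only, and a second network trained at scales 0.65, 1 and 1.5.
#'
#' @param cfg An [experiment_config()].
#' @param basis An `encoding_basis`.
#' @param noise A [noise_model()].
#' @param net_spec An [mlp_spec()] for the discriminator.
#' @param criterion Percent-correct criterion (default 75).
#' @param seed RNG seed.
#' @param noise_space Passed to [build_trials()].
#' @return A list with the psychometric `curve` (per protocol for
#'   experiment 3), the `threshold` in the experiment's difficulty units
#'   (us for 1, kHz of notch separation for 2, degrees for 4), and the
#'   trained model(s).
#' @export
run_experiment <- function(cfg, basis, noise, net_spec = discriminator_spec(),
                           criterion = 75, seed = 1L,
                           noise_space = "code") {
  if (is.null(cfg$ref_gain))
    cfg$ref_gain <- calibrate_reference_gain(cfg$fb_spec, cfg$em_spec)
  run_one <- function(cfg, seed_off = 0L) {
    trials <- build_trials(cfg, basis, noise, seed = child_seed(seed, seed_off),
                           noise_space = noise_space)
    model <- train_discriminator(trials, net_spec)
    list(trials = trials, model = model,
         curve = psychometric(model, trials, criterion))
  }
  if (cfg$experiment == 3L) {
    p1 <- run_one(cfg, 1L)
    cfg2 <- cfg
    cfg2$train_scales <- c(min(cfg$scales), 1, max(cfg$scales))
    p2 <- run_one(cfg2, 2L)
    return(list(experiment = 3L,
                curve = p1$curve, curve_generalization = p2$curve,
                model = p1$model, model_generalization = p2$model,
                criterion = criterion))
  }
  r <- run_one(cfg, 1L)
  th <- switch(as.character(cfg$experiment),
    "1" = threshold_from_curve(r$curve$condition, r$curve$pct_correct,
                               criterion),
    "2" = {
      fc <- fold_curve(r$curve, center = cfg$rewarded_notch)
      fc <- fc[fc$difficulty > 0, ]
      c(threshold_from_curve(fc$difficulty / 1000, fc$x, criterion),
        list(folded = fc))
    },
    "4" = {
      fc <- fold_curve(r$curve)
      fc <- fc[fc$difficulty > 0, ]
      c(threshold_from_curve(fc$difficulty, fc$x, criterion),
        list(folded = fc))
    })
  list(experiment = cfg$experiment, curve = r$curve,
       threshold = th$threshold, threshold_status = th$status,
       folded = th$folded, model = r$model, criterion = criterion)
}
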