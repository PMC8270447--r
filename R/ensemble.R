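# Synthetic echo ensembles with the statistical structure of field
# recordings: a fixed set of "locations" (scenes), each a collection of
# reflecting glints, ensonified from jittered poses with three noisy repeat
# measurements per pose. Glint amplitudes carry two-way spherical spreading;
# echo synthesis applies frequency-dependent atmospheric absorption per
# glint, so distant reflectors are low-pass shaped relative to near ones.

#' Acoustic propagation parameters
#'
#' Absorption follows a power law `alpha(f) = alpha0 * (f / ref_freq)^power`
#' in dB/m (monotone increasing in frequency); spreading is `1 / r^exponent`
#' in amplitude for the two-way path.
#'
#' @param speed_of_sound Speed of sound in m/s.
#' @param spreading_exponent Two-way spreading exponent (2 = spherical,
#'   amplitude `1/r^2`).
#' @param alpha0_db_per_m Absorption at the reference frequency, dB/m.
#' @param alpha_ref_freq Reference frequency in Hz.
#' @param alpha_power Power-law exponent (> 0).
#' @return An object of class `propagation_model`.
#' @export
propagation_model <- function(speed_of_sound = 343, spreading_exponent = 2,
                              alpha0_db_per_m = 1.0, alpha_ref_freq = 35000,
                              alpha_power = 1.6) {
  if (spreading_exponent <= 0) stop("`spreading_exponent` must be > 0")
  if (alpha0_db_per_m < 0 || alpha_power < 0)
    stop("absorption parameters must be nonnegative")
  structure(list(speed_of_sound = speed_of_sound,
                 spreading_exponent = spreading_exponent,
                 alpha0_db_per_m = alpha0_db_per_m,
                 alpha_ref_freq = alpha_ref_freq, alpha_power = alpha_power),
            class = "propagation_model")
}

# absorption in dB/m at frequency f (Hz), vectorized
#' @keywords internal
absorption_db_per_m <- function(model, f) {
  model$alpha0_db_per_m * (abs(f) / model$alpha_ref_freq)^model$alpha_power
}

#' Location (scene) specification
#'
#' A location is a fixed set of reflecting glints at ranges within the sonar
#' reach, in one of two regimes: `sparse_glints` (few strong, stable
#' reflectors: man-made/indoor scenes) or `dense_stochastic` (many weak,
#' rough reflectors: foliage). The scene itself (`$scene`) is drawn once
#' when the spec is materialized; per-echo impulse responses jitter it.
#'
#' @param id Location identifier.
#' @param regime `"sparse_glints"` or `"dense_stochastic"`.
#' @param n_glints_mean Mean glint count (Poisson for the dense regime,
#'   fixed for the sparse regime).
#' @param range Length-2 range interval in meters (within 0-3.2 m).
#' @param pose_jitter Std dev of the common range displacement between
#'   poses, meters.
#' @param glint_jitter Std dev of per-glint range jitter between poses,
#'   meters (scene roughness).
#' @param reflect_jitter Lognormal sd of per-pose reflectivity fluctuation.
#' @param sibling_of Optional id of a deliberately similar location.
#' @param seed Seed used to draw the scene.
#' @return An object of class `location_spec` with the drawn `$scene`
#'   (data frame of `range`, `reflectivity`).
#' @export
location_spec <- function(id, regime = c("sparse_glints", "dense_stochastic"),
                          n_glints_mean = NULL, range = c(0.4, 3.0),
                          pose_jitter = 0.005, glint_jitter = NULL,
                          reflect_jitter = NULL, sibling_of = NULL,
                          seed = 1L) {
  regime <- match.arg(regime)
  if (range[1] <= 0 || range[2] > 3.2 || range[1] >= range[2])
    stop("`range` must be an increasing interval within (0, 3.2] m")
  if (is.null(n_glints_mean))
    n_glints_mean <- if (regime == "sparse_glints") 4 else 25
  if (is.null(glint_jitter))
    glint_jitter <- if (regime == "sparse_glints") 0.001 else 0.002
  if (is.null(reflect_jitter))
    reflect_jitter <- if (regime == "sparse_glints") 0.04 else 0.06
  scene <- with_rng_seed(seed, {
    n <- if (regime == "sparse_glints") max(1L, round(n_glints_mean))
         else max(1L, stats::rpois(1, n_glints_mean))
    data.frame(range = stats::runif(n, range[1], range[2]),
               reflectivity = if (regime == "sparse_glints")
                 stats::runif(n, 0.5, 1.5) else stats::rexp(n, 1))
  })
  structure(list(id = id, regime = regime, n_glints_mean = n_glints_mean,
                 range = range, pose_jitter = pose_jitter,
                 glint_jitter = glint_jitter, reflect_jitter = reflect_jitter,
                 sibling_of = sibling_of, scene = scene, seed = seed),
            class = "location_spec")
}

# derive a sibling location: same scene, slightly perturbed
#' @keywords internal
sibling_location <- function(loc, id, seed) {
  out <- loc
  out$id <- id
  out$sibling_of <- loc$id
  out$seed <- seed
  out$scene <- with_rng_seed(seed, {
    sc <- loc$scene
    sc$range <- pmin(pmax(sc$range + stats::rnorm(nrow(sc), 0, 0.004),
                          loc$range[1]), loc$range[2])
    sc$reflectivity <- sc$reflectivity * exp(stats::rnorm(nrow(sc), 0, 0.05))
    sc
  })
  out
}

#' Default set of 21 locations
#'
#' Roughly half sparse ("indoor") and half dense ("foliage") scenes, with a
#' few sibling pairs — locations sharing nearly the same reflector layout —
#' to emulate confusable places (different rooms of one building, adjacent
#' field sites).
#'
#' @param n_locations Number of locations.
#' @param n_indoor Number of sparse-regime locations.
#' @param n_sibling_pairs Number of sibling pairs to embed.
#' @param seed RNG seed.
#' @return A list of `location_spec`s.
#' @export
default_location_specs <- function(n_locations = 21L, n_indoor = 11L,
                                   n_sibling_pairs = 3L, seed = 1L) {
  if (n_indoor > n_locations) stop("`n_indoor` exceeds `n_locations`")
  regimes <- c(rep("sparse_glints", n_indoor),
               rep("dense_stochastic", n_locations - n_indoor))
  locs <- lapply(seq_len(n_locations), function(i)
    location_spec(id = sprintf("loc%02d", i), regime = regimes[i],
                  seed = child_seed(seed, i)))
  # overwrite the last member of each pair with a sibling of the previous one
  if (n_sibling_pairs > 0) {
    pick <- head(seq(2L, n_locations, by = 2L), n_sibling_pairs)
    for (i in pick)
      locs[[i]] <- sibling_location(locs[[i - 1L]], locs[[i]]$id,
                                    child_seed(seed, 1000L + i))
  }
  locs
}

#' Draw one echo's impulse response from a location
#'
#' Applies a common pose displacement plus per-glint range and reflectivity
#' jitter to the location's scene; glint amplitude is the two-way spreading
#' attenuation at its range times the reflectivity.
#'
#' @param loc A `location_spec`.
#' @param seed RNG seed (one seed per pose).
#' @param model A [propagation_model()].
#' @return An `impulse_response` with a `ranges` attribute (meters).
#' @export
sample_location_ir <- function(loc, seed = NULL, model = propagation_model()) {
  if (!inherits(loc, "location_spec")) stop("`loc` must be a location_spec")
  with_rng_seed(seed, {
    sc <- loc$scene
    r <- sc$range + stats::rnorm(1, 0, loc$pose_jitter) +
      stats::rnorm(nrow(sc), 0, loc$glint_jitter)
    r <- pmin(pmax(r, 0.1), 3.2)
    refl <- sc$reflectivity * exp(stats::rnorm(nrow(sc), 0, loc$reflect_jitter))
    amp <- refl / r^model$spreading_exponent
    ir <- impulse_response(2 * r / model$speed_of_sound, amp)
    attr(ir, "ranges") <- r[order(2 * r)]
    ir
  })
}

#' Apply atmospheric absorption (and optionally spreading) to an echo
#'
#' Spectrally shapes the waveform by `10^(-alpha(f) * 2 r / 20)` for a
#' single propagation range `r` (two-way path). Spreading is off by default
#' because [sample_location_ir()] already folds it into glint amplitudes.
#'
#' @param echo An `echo_wave`.
#' @param range Propagation range in meters (one-way).
#' @param model A [propagation_model()].
#' @param apply_spreading Also multiply by `1 / range^spreading_exponent`.
#' @return The filtered `echo_wave`.
#' @export
propagate <- function(echo, range, model = propagation_model(),
                      apply_spreading = FALSE) {
  if (!inherits(echo, "echo_wave")) stop("`echo` must be an echo_wave")
  stopifnot_scalar(range, "range", positive = TRUE)
  n <- length(echo$samples)
  nfft <- next_pow2(2L * n)
  f <- (seq_len(nfft) - 1L) / nfft * echo$fs
  f[f > echo$fs / 2] <- f[f > echo$fs / 2] - echo$fs
  H <- db_to_lin(-absorption_db_per_m(model, f) * 2 * range)
  X <- stats::fft(c(echo$samples, numeric(nfft - n)))
  y <- Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
  if (apply_spreading) y <- y / range^model$spreading_exponent
  echo_wave(y, fs = echo$fs, t0 = echo$t0)
}

# band-limited synthesis of a field echo with per-glint absorption shaping
#' @keywords internal
field_echo <- function(ir, emission, model) {
  ranges <- attr(ir, "ranges")
  if (is.null(ranges)) ranges <- ir$delays * model$speed_of_sound / 2
  fs <- emission$fs
  n_out <- window_samples(fs)
  nfft <- next_pow2(n_out + length(emission$samples) + 64L)
  E <- stats::fft(c(emission$samples, numeric(nfft - length(emission$samples))))
  f <- (seq_len(nfft) - 1L) / nfft * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  H <- 0
  for (g in seq_along(ir$delays)) {
    A <- db_to_lin(-absorption_db_per_m(model, f) * 2 * ranges[g])
    H <- H + ir$amplitudes[g] * A * exp(-2i * pi * f * ir$delays[g])
  }
  x <- Re(stats::fft(E * H, inverse = TRUE))[seq_len(n_out)] / nfft
  echo_wave(x, fs = fs, t0 = 0)
}

#' Generate a labeled synthetic echo dataset
#'
#' Per location, draws a number of poses; per pose, draws a jittered
#' impulse response, synthesizes the clean echo with per-glint absorption,
#' and records `repeats` measurements differing only by additive white
#' measurement noise — destined for cochleogram averaging.
#'
#' @param locations List of `location_spec`s.
#' @param poses_per_location Length-2 inclusive range of poses per location
#'   (each pose yields `repeats` echoes), or a vector of one count per
#'   location.
#' @param repeats Measurements per pose.
#' @param measurement_snr_db Waveform signal-to-noise ratio of each
#'   measurement in dB.
#' @param emission Emission `echo_wave`.
#' @param model A [propagation_model()].
#' @param seed RNG seed.
#' @param preset `"paper"` reproduces the field campaign's bookkeeping:
#'   1014 echoes = 338 poses x 3 repeats over 21 locations, about 500 of
#'   them from the 11 sparse ("indoor") locations.
#' @return An object of class `echo_dataset`: `$echoes` (list of
#'   `echo_wave`s), `$location`, `$pose`, `$rep` (parallel vectors), the
#'   `$locations` specs and a `$manifest` of the generation parameters.
#' @export
generate_dataset <- function(locations = default_location_specs(seed = seed),
                             poses_per_location = c(10L, 16L), repeats = 3L,
                             measurement_snr_db = 30,
                             emission = make_emission(),
                             model = propagation_model(), seed = 1L,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "paper")
    locations <- default_location_specs(n_locations = 21L, n_indoor = 11L,
                                        seed = seed)
    # 338 poses x 3 repeats = 1014 echoes; 167 indoor poses ~ 500 indoor echoes
    poses_per_location <- c(rep(15L, 9L), 16L, 16L,   # indoor: 167 poses
                            rep(17L, 9L), 18L)        # outdoor: 171 poses
    repeats <- 3L
  }
  nl <- length(locations)
  n_poses <- if (length(poses_per_location) == nl) poses_per_location
  else with_rng_seed(child_seed(seed, 0L),
                     sample(poses_per_location[1]:poses_per_location[2],
                            nl, replace = TRUE))
  echoes <- list(); location <- character(); pose <- integer(); rp <- integer()
  pose_id <- 0L
  for (i in seq_len(nl)) {
    loc <- locations[[i]]
    for (p in seq_len(n_poses[i])) {
      pose_id <- pose_id + 1L
      s <- child_seed(seed, pose_id)
      ir <- sample_location_ir(loc, seed = s, model = model)
      clean <- field_echo(ir, emission, model)
      noise_sd <- sqrt(mean(clean$samples^2)) * db_to_lin(-measurement_snr_db)
      reps <- with_rng_seed(child_seed(s, 1L), lapply(seq_len(repeats),
        function(r) echo_wave(clean$samples +
                                stats::rnorm(length(clean$samples), 0, noise_sd),
                              fs = clean$fs)))
      echoes <- c(echoes, reps)
      location <- c(location, rep(loc$id, repeats))
      pose <- c(pose, rep(pose_id, repeats))
      rp <- c(rp, seq_len(repeats))
    }
  }
  structure(list(echoes = echoes, location = factor(location), pose = pose,
                 rep = rp, locations = locations,
                 manifest = list(seed = seed, repeats = repeats,
                                 measurement_snr_db = measurement_snr_db,
                                 n_poses = n_poses, preset = preset)),
            class = "echo_dataset")
}

#' @export
print.echo_dataset <- function(x, ...) {
  cat(sprintf("<echo_dataset> %d echoes (%d poses x %d repeats) at %d locations\n",
              length(x$echoes), length(unique(x$pose)), x$manifest$repeats,
              nlevels(x$location)))
  invisible(x)
}

#' Convert a dataset to dechirped, repeat-averaged cochleograms
#'
#' Runs the peripheral model on every echo, dechirps, and averages the
#' repeats of each pose.
#'
#' @param dataset An `echo_dataset`.
#' @param spec A [filterbank_spec()].
#' @param emission An [emission_spec()] for dechirping.
#' @param average Average the repeats of each pose (default TRUE).
#' @return A list with `$cochs` (list of `cochleogram`s), `$labels`
#'   (location factor, one per cochleogram) and `$pose`.
#' @export
ensemble_cochleograms <- function(dataset, spec = filterbank_spec(),
                                  emission = emission_spec(),
                                  average = TRUE) {
  if (!inherits(dataset, "echo_dataset")) stop("`dataset` must be an echo_dataset")
  cochs <- lapply(dataset$echoes, function(e) dechirp(cochleagram(e, spec),
                                                      emission))
  if (!average)
    return(list(cochs = cochs, labels = dataset$location, pose = dataset$pose))
  poses <- unique(dataset$pose)
  avg <- lapply(poses, function(p)
    average_repeats(cochs[dataset$pose == p]))
  labels <- dataset$location[match(poses, dataset$pose)]
  list(cochs = avg, labels = droplevels(labels), pose = poses)
}
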