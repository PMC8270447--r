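# Internal-noise model: iid zero-mean Gaussian noise added to cochleogram
# samples, with its standard deviation calibrated so that a 5 dB echo-level
# step is discriminated at the behavioral intensity-JND rate (70 % correct
# by default) using the summed-cochleogram decision statistic.

#' Internal-noise model
#'
#' @param sigma Standard deviation of the per-sample Gaussian noise, in
#'   model units (>= 0).
#' @param seed Optional RNG seed used by [add_noise()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = NULL) {
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma = %.4g m.u.\n", x$sigma))
  invisible(x)
}

#' Add internal noise to a cochleogram
#'
#' Adds iid `N(0, sigma)` to every sample. Values are not clipped, so noisy
#' cochleograms may contain negative entries.
#'
#' @param coch A `cochleogram`.
#' @param model A [noise_model()].
#' @return The noisy `cochleogram`.
#' @export
add_noise <- function(coch, model) {
  if (!inherits(coch, "cochleogram")) stop("`coch` must be a cochleogram")
  if (!inherits(model, "noise_model")) stop("`model` must be a noise_model")
  if (model$sigma == 0) return(coch)
  with_rng_seed(model$seed, {
    coch$values <- coch$values +
      matrix(stats::rnorm(length(coch$values), 0, model$sigma),
             nrow = nrow(coch$values))
    coch$reconstructed <- TRUE  # nonnegativity no longer guaranteed
    coch
  })
}

#' Intensity discrimination probability under summed-cochleogram noise
#'
#' Monte-Carlo estimate of `P[sum(S_plus + N) > sum(S_ref + N')]` with
#' independent noise fields per stimulus per trial. The per-stimulus noise
#' sum over the K samples is itself exactly Gaussian with variance
#' `K sigma^2`, and is sampled from that law directly.
#'
#' @param s_ref,s_plus Reference and incremented `cochleogram`s (same shape).
#' @param sigma Noise standard deviation (m.u.).
#' @param n_mc Number of Monte-Carlo trials (>= 1000).
#' @param seed RNG seed.
#' @return Estimated probability in `[0, 1]`.
#' @export
discrimination_probability <- function(s_ref, s_plus, sigma, n_mc = 20000L,
                                       seed = 1L) {
  if (!inherits(s_ref, "cochleogram") || !inherits(s_plus, "cochleogram"))
    stop("`s_ref` and `s_plus` must be cochleograms")
  if (!identical(dim(s_ref$values), dim(s_plus$values)))
    stop("cochleogram shapes differ")
  if (n_mc < 1000L) stop("`n_mc` must be >= 1000")
  delta <- sum(s_plus$values) - sum(s_ref$values)
  if (sigma == 0) return(as.numeric(delta > 0))
  k <- length(s_ref$values)
  with_rng_seed(seed, {
    n_plus <- stats::rnorm(n_mc, 0, sigma * sqrt(k))
    n_ref <- stats::rnorm(n_mc, 0, sigma * sqrt(k))
    mean(delta + n_plus - n_ref > 0)
  })
}

#' Calibrate the internal-noise level against an intensity JND
#'
#' Bisection on `sigma` (the discrimination probability is monotone
#' non-increasing in it) until the louder stimulus is told apart from the
#' reference with probability `target_p` (within `tol_p`).
#'
#' @param s_ref Reference `cochleogram`.
#' @param s_plus Cochleogram of the stimulus at the JND level step (e.g. a
#'   +5 dB input level).
#' @param target_p Target probability correct, in (0.5, 1).
#' @param n_mc Monte-Carlo trials per probe.
#' @param seed RNG seed (common random numbers across probes keep the
#'   search monotone).
#' @param tol_p Probability tolerance.
#' @return The calibrated `sigma` (m.u.).
#' @export
calibrate_sigma <- function(s_ref, s_plus, target_p = 0.70, n_mc = 20000L,
                            seed = 1L, tol_p = 0.01) {
  if (target_p <= 0.5 || target_p >= 1)
    stop("`target_p` must lie strictly between 0.5 and 1")
  delta <- sum(s_plus$values) - sum(s_ref$values)
  if (delta <= 0)
    stop("`s_plus` must have a larger cochleogram sum than `s_ref`")
  k <- length(s_ref$values)
  p_at <- function(sig)
    discrimination_probability(s_ref, s_plus, sig, n_mc = n_mc, seed = seed)
  # analytic first guess, then bracket
  sig <- delta / (sqrt(2 * k) * stats::qnorm(target_p))
  lo <- sig / 64; hi <- sig * 64
  while (p_at(hi) > target_p) hi <- hi * 4
  while (p_at(lo) < target_p) lo <- lo / 4
  for (i in seq_len(80L)) {
    mid <- sqrt(lo * hi)
    p <- p_at(mid)
    if (abs(p - target_p) <= tol_p) return(mid)
    if (p > target_p) lo <- mid else hi <- mid
  }
  stats::setNames(sqrt(lo * hi), "sigma_unconverged")
}
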