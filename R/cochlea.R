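# Peripheral auditory model: gammatone filterbank, half-wave rectification,
# power-law compression, 1 kHz low-pass, dechirping and repeat averaging.
#
# Channels are 4th-order gammatone filters realized as FIR impulse responses
# (unit peak magnitude response), center frequencies equally spaced on the
# ERB-rate scale across the sonar passband. The Glasberg-Moore ERB formula
# is extrapolated to ultrasonic frequencies.

#' Equivalent rectangular bandwidth scale (Glasberg-Moore)
#'
#' `erb_hz` gives the equivalent rectangular bandwidth (Hz) at a center
#' frequency; `erb_rate` maps frequency to the ERB-rate (ERB-number) scale
#' and `erb_rate_inv` inverts it. The formula is extrapolated to the
#' ultrasonic sonar band.
#'
#' @param f Frequency in Hz.
#' @param e ERB-rate value.
#' @return Bandwidth in Hz, ERB-rate, or frequency in Hz respectively.
#' @export
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' @rdname erb_hz
#' @export
erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_hz
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Filterbank and cochlear-model parameters
#'
#' @param n_channels Number of frequency channels.
#' @param f_min,f_max Passband edges in Hz; default 16-70 kHz (the sonar
#'   system's passband). Centers are equally spaced in ERB-rate between them.
#' @param center_freqs Optional explicit ascending center frequencies (Hz),
#'   overriding the ERB spacing.
#' @param fs Design sample rate in Hz.
#' @param gammatone_order Gammatone filter order.
#' @param compression_exponent Power-law compression exponent in (0, 1].
#' @param lp_cutoff Envelope low-pass cutoff in Hz.
#' @param n_taps Gammatone FIR length in samples.
#' @return An object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(n_channels = 20L, f_min = 16000, f_max = 70000,
                            center_freqs = NULL, fs = DEFAULT_FS,
                            gammatone_order = 4L, compression_exponent = 0.4,
                            lp_cutoff = 1000, n_taps = 1024L) {
  if (is.null(center_freqs)) {
    e <- seq(erb_rate(f_min), erb_rate(f_max), length.out = n_channels)
    center_freqs <- erb_rate_inv(e)
  } else {
    n_channels <- length(center_freqs)
  }
  if (is.unsorted(center_freqs, strictly = TRUE))
    stop("center frequencies must be strictly ascending")
  if (compression_exponent <= 0 || compression_exponent > 1)
    stop("`compression_exponent` must be in (0, 1]")
  stopifnot_scalar(lp_cutoff, "lp_cutoff", positive = TRUE)
  structure(list(n_channels = as.integer(n_channels),
                 center_freqs = as.numeric(center_freqs), fs = fs,
                 gammatone_order = as.integer(gammatone_order),
                 compression_exponent = compression_exponent,
                 lp_cutoff = lp_cutoff, n_taps = as.integer(n_taps)),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf(paste0("<filterbank_spec> %d gammatone channels, %.1f-%.1f kHz,",
                     " order %d, gamma %.2f, LP %.0f Hz @ %.0f kHz\n"),
              x$n_channels, min(x$center_freqs) / 1000,
              max(x$center_freqs) / 1000, x$gammatone_order,
              x$compression_exponent, x$lp_cutoff, x$fs / 1000))
  invisible(x)
}

# gammatone FIR impulse response at fc, peak magnitude response normalized to 1
#' @keywords internal
gammatone_fir <- function(fc, fs, order, n_taps) {
  t <- (seq_len(n_taps) - 1L) / fs
  b <- 1.019 * erb_hz(fc)
  h <- t^(order - 1L) * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  h / max(Mod(stats::fft(c(h, numeric(n_taps)))))
}

# cache of designed filterbanks keyed by spec parameters
.fb_cache <- new.env(parent = emptyenv())

#' @keywords internal
filterbank_fft <- function(spec, nfft) {
  key <- paste(c(spec$center_freqs, spec$fs, spec$gammatone_order,
                 spec$n_taps, nfft), collapse = "|")
  hit <- get0(key, envir = .fb_cache)
  if (!is.null(hit)) return(hit)
  H <- sapply(spec$center_freqs, function(fc) {
    h <- gammatone_fir(fc, spec$fs, spec$gammatone_order, spec$n_taps)
    stats::fft(c(h, numeric(nfft - spec$n_taps)))
  })
  assign(key, H, envir = .fb_cache)
  H
}

#' Compute a cochleogram
#'
#' Per channel: gammatone bandpass, half-wave rectification, power-law
#' compression `x^gamma`, then a causal 2nd-order Butterworth low-pass at
#' `lp_cutoff`. The (slightly undershooting) low-pass output is clamped at
#' zero so cochleograms are nonnegative model units.
#'
#' @param echo An `echo_wave` of exactly [window_samples()] samples at the
#'   spec's design rate.
#' @param spec A [filterbank_spec()].
#' @return An object of class `cochleogram` holding a `n_channels x n_samples`
#'   matrix (`$values`), channel frequencies and the spec.
#' @export
cochleagram <- function(echo, spec = filterbank_spec()) {
  if (!inherits(echo, "echo_wave")) stop("`echo` must be an echo_wave")
  if (!inherits(spec, "filterbank_spec")) stop("`spec` must be a filterbank_spec")
  if (echo$fs != spec$fs)
    stop(sprintf("echo sample rate (%g) does not match the filterbank design rate (%g)",
                 echo$fs, spec$fs))
  n <- window_samples(spec$fs)
  if (length(echo$samples) != n)
    stop(sprintf("echo must be exactly %d samples long (got %d)",
                 n, length(echo$samples)))
  nfft <- next_pow2(n + spec$n_taps)
  H <- filterbank_fft(spec, nfft)
  X <- stats::fft(c(echo$samples, numeric(nfft - n)))
  bf <- signal::butter(2, spec$lp_cutoff / (spec$fs / 2), type = "low")
  vals <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (k in seq_len(spec$n_channels)) {
    y <- Re(stats::fft(X * H[, k], inverse = TRUE))[seq_len(n)] / nfft
    r <- pmax(y, 0)^spec$compression_exponent
    vals[k, ] <- pmax(as.numeric(signal::filter(bf, r)), 0)
  }
  new_cochleogram(vals, spec, dechirped = FALSE)
}

#' @keywords internal
new_cochleogram <- function(values, spec, dechirped,
                            reconstructed = FALSE) {
  structure(list(values = values, fs = spec$fs,
                 channel_freqs = spec$center_freqs, spec = spec,
                 dechirped = dechirped, reconstructed = reconstructed),
            class = "cochleogram")
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf("<cochleogram> %d x %d (%sdechirped), max %.3g m.u.\n",
              nrow(x$values), ncol(x$values),
              if (x$dechirped) "" else "not ", max(x$values)))
  invisible(x)
}

#' Dechirp a cochleogram
#'
#' Advances each channel by the time at which the emission's downward sweep
#' crosses that channel's center frequency (clamped to the sweep duration at
#' the band edges), aligning all channels' responses to a single reflector.
#' Shifts are rounded to integer samples; vacated tail samples are zero.
#'
#' @param coch A `cochleogram` (not yet dechirped).
#' @param emission An [emission_spec()] describing the sweep.
#' @return The dechirped `cochleogram`.
#' @export
dechirp <- function(coch, emission = emission_spec()) {
  if (!inherits(coch, "cochleogram")) stop("`coch` must be a cochleogram")
  if (coch$dechirped) stop("cochleogram is already dechirped")
  if (!inherits(emission, "emission_spec"))
    stop("`emission` must be an emission_spec")
  n <- ncol(coch$values)
  shifts <- round(emission_time_at_freq(emission, coch$channel_freqs) * coch$fs)
  vals <- coch$values
  for (k in seq_len(nrow(vals))) {
    s <- shifts[k]
    if (s > 0) vals[k, ] <- c(vals[k, (s + 1L):n], numeric(s))
  }
  out <- coch
  out$values <- vals
  out$dechirped <- TRUE
  out
}

#' Average repeated measurements
#'
#' Element-wise mean of cochleograms from repeated ensonifications of the
#' same pose, raising the signal-to-noise ratio.
#'
#' @param cochs A list of `cochleogram`s with identical shape and flags.
#' @return The mean `cochleogram`.
#' @export
average_repeats <- function(cochs) {
  if (!is.list(cochs) || length(cochs) < 1L ||
      !all(vapply(cochs, inherits, logical(1), "cochleogram")))
    stop("`cochs` must be a non-empty list of cochleograms")
  d <- dim(cochs[[1]]$values)
  flag <- cochs[[1]]$dechirped
  for (cc in cochs) {
    if (!identical(dim(cc$values), d)) stop("cochleogram shapes differ")
    if (!identical(cc$dechirped, flag)) stop("dechirped flags differ")
  }
  out <- cochs[[1]]
  out$values <- Reduce(`+`, lapply(cochs, `[[`, "values")) / length(cochs)
  out
}

#' Waveform gain normalizing an ensemble's cochleogram ceiling
#'
#' Returns the input-domain (waveform) gain which, applied to every echo and
#' after recomputing cochleograms, brings the ensemble's maximum cochleogram
#' value to `target_max`. Because the model is homogeneous of degree gamma in
#' input amplitude, the gain is `(target_max / current_max)^(1/gamma)`.
#'
#' @param ensemble A non-empty list of `cochleogram`s.
#' @param target_max Target ceiling in model units (default 15).
#' @return The scalar waveform gain.
#' @export
normalize_reference_level <- function(ensemble, target_max = 15) {
  if (!is.list(ensemble) || length(ensemble) < 1L)
    stop("`ensemble` must be a non-empty list of cochleograms")
  stopifnot_scalar(target_max, "target_max", positive = TRUE)
  m <- max(vapply(ensemble, function(cc) max(cc$values), numeric(1)))
  if (m <= 0) stop("cannot normalize an all-zero ensemble")
  gamma <- ensemble[[1]]$spec$compression_exponent
  (target_max / m)^(1 / gamma)
}

#' Rescale a cochleogram as if the input waveform had been amplified
#'
#' Applying a waveform gain `g` scales every cochleogram value by exactly
#' `g^gamma` (the model is homogeneous of degree gamma in input amplitude),
#' so the cochleogram never needs to be recomputed after a level change.
#'
#' @param coch A `cochleogram`.
#' @param gain Waveform (input-domain) gain, linear.
#' @return The rescaled `cochleogram`.
#' @export
scale_cochleogram <- function(coch, gain) {
  coch$values <- coch$values * gain^coch$spec$compression_exponent
  coch
}
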