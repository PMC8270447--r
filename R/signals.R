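# Emission, phantom-target impulse responses and echo synthesis.
#
# All phantom-target stimuli live in a fixed analysis window of 7000 samples
# at 360 kHz (19.44 ms), matching the 20 x 7000 cochleogram geometry. Glint
# delays are continuous; echo synthesis is band-limited (frequency-domain),
# so microsecond-scale inter-glint delays are represented exactly rather
# than rounded to the sample grid.

DEFAULT_FS <- 360000
WINDOW_N <- 7000L

#' Analysis-window length in samples for a given sample rate
#'
#' The canonical window is 7000 samples at 360 kHz (19.44 ms); other rates
#' get the same duration.
#'
#' @param fs Sample rate in Hz.
#' @return Integer number of samples.
#' @export
window_samples <- function(fs = DEFAULT_FS) {
  as.integer(round(fs * WINDOW_N / DEFAULT_FS))
}

#' Sampled pressure waveform
#'
#' @param samples Numeric vector of pressure samples (arbitrary linear units).
#' @param fs Sample rate in Hz.
#' @param t0 Start time of the window in seconds.
#' @return An object of class `echo_wave`.
#' @export
echo_wave <- function(samples, fs = DEFAULT_FS, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  stopifnot_scalar(fs, "fs", positive = TRUE)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "echo_wave")
}

#' @export
print.echo_wave <- function(x, ...) {
  cat(sprintf("<echo_wave> %d samples @ %.0f kHz (%.2f ms), peak %.3g\n",
              length(x$samples), x$fs / 1000,
              1000 * length(x$samples) / x$fs, max(abs(x$samples))))
  invisible(x)
}

#' Emission call parameters
#'
#' A downward hyperbolic (linear-period) FM sweep, the Doppler-tolerant call
#' type used by many FM bats. Defaults: 1 ms, 70 kHz down to 30 kHz.
#'
#' @param duration Sweep duration in seconds.
#' @param f_hi Start (high) frequency in Hz.
#' @param f_lo End (low) frequency in Hz.
#' @param sweep Sweep type; only `"hyperbolic"` is defined.
#' @return An object of class `emission_spec`.
#' @export
emission_spec <- function(duration = 1e-3, f_hi = 70000, f_lo = 30000,
                          sweep = "hyperbolic") {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(f_hi, "f_hi", positive = TRUE)
  stopifnot_scalar(f_lo, "f_lo", positive = TRUE)
  sweep <- match.arg(sweep, "hyperbolic")
  if (!(f_hi > f_lo)) stop("`f_hi` must exceed `f_lo`")
  structure(list(duration = duration, f_hi = f_hi, f_lo = f_lo, sweep = sweep),
            class = "emission_spec")
}

# instantaneous frequency of the hyperbolic sweep at time t (vectorized);
# linear-in-period: 1/f(t) = 1/f_hi + (1/f_lo - 1/f_hi) t / T
#' @keywords internal
emission_instantaneous_freq <- function(spec, t) {
  a <- 1 / spec$f_hi
  b <- (1 / spec$f_lo - 1 / spec$f_hi) / spec$duration
  1 / (a + b * pmax(pmin(t, spec$duration), 0))
}

# time at which the sweep crosses frequency f (clamped to [0, T])
#' @keywords internal
emission_time_at_freq <- function(spec, f) {
  a <- 1 / spec$f_hi
  b <- (1 / spec$f_lo - 1 / spec$f_hi) / spec$duration
  pmax(pmin((1 / f - a) / b, spec$duration), 0)
}

#' Synthesize the emission call
#'
#' Unit-peak hyperbolic chirp: the instantaneous period grows linearly in
#' time from `1/f_hi` to `1/f_lo`; the phase is the cumulative integral of
#' the instantaneous frequency.
#'
#' @param spec An [emission_spec()].
#' @param fs Sample rate in Hz; must satisfy `fs >= 2 * f_hi`.
#' @return An `echo_wave` of `round(duration * fs)` samples.
#' @export
make_emission <- function(spec = emission_spec(), fs = DEFAULT_FS) {
  if (!inherits(spec, "emission_spec")) stop("`spec` must be an emission_spec")
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs < 2 * spec$f_hi)
    stop(sprintf("sample rate %.0f Hz is below Nyquist for f_hi = %.0f Hz",
                 fs, spec$f_hi))
  n <- as.integer(round(spec$duration * fs))
  t <- (seq_len(n) - 1L) / fs
  a <- 1 / spec$f_hi
  b <- (1 / spec$f_lo - 1 / spec$f_hi) / spec$duration
  # phase(t) = 2*pi * integral of 1/(a + b u) du = (2*pi/b) * log(1 + b t / a)
  phase <- (2 * pi / b) * log1p(b * t / a)
  x <- sin(phase)
  echo_wave(x / max(abs(x)), fs = fs, t0 = 0)
}

#' Phantom-target impulse response
#'
#' A sparse list of reflective glints, each a (delay, amplitude) pair. Delays
#' are seconds from the emission instant and must fall inside the analysis
#' window; amplitudes are dimensionless linear gains, nonnegative unless
#' `allow_negative` is set.
#'
#' @param delays Glint delays in seconds.
#' @param amplitudes Linear amplitudes, same length as `delays`.
#' @param allow_negative Permit negative amplitudes (phase-inverting glints).
#' @return An object of class `impulse_response`.
#' @export
impulse_response <- function(delays, amplitudes, allow_negative = FALSE) {
  if (length(delays) < 1L) stop("an impulse response needs at least one glint")
  if (length(delays) != length(amplitudes))
    stop("`delays` and `amplitudes` must have the same length")
  if (!all(is.finite(delays)) || !all(is.finite(amplitudes)))
    stop("glint delays and amplitudes must be finite")
  win <- WINDOW_N / DEFAULT_FS
  if (any(delays < 0) || any(delays >= win))
    stop(sprintf("glint delays must lie in [0, %.4f) s (the analysis window)", win))
  if (!allow_negative && any(amplitudes < 0))
    stop("negative glint amplitudes are not allowed by default")
  o <- order(delays)
  structure(list(delays = as.numeric(delays)[o],
                 amplitudes = as.numeric(amplitudes)[o]),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d glint(s), delays %.3f-%.3f ms\n",
              length(x$delays), 1000 * min(x$delays), 1000 * max(x$delays)))
  invisible(x)
}

#' Single-glint impulse response
#'
#' @param delay Glint delay in seconds.
#' @param gain_db Glint level in dB re. unit amplitude.
#' @return An `impulse_response` with one glint of amplitude `10^(gain_db/20)`.
#' @export
single_glint_ir <- function(delay, gain_db = 0) {
  stopifnot_scalar(delay, "delay")
  stopifnot_scalar(gain_db, "gain_db")
  impulse_response(delay, db_to_lin(gain_db))
}

#' Two-glint stimulus parameters
#'
#' The classic double-reflector phantom target: a leading glint at
#' `base_delay` and a trailing glint `tau` seconds later with relative
#' amplitude `a`.
#'
#' @param tau Inter-glint delay in seconds (> 0).
#' @param a Linear amplitude of the trailing glint relative to the leading one.
#' @param base_delay Delay of the leading glint in seconds.
#' @return An object of class `two_glint_spec`.
#' @export
two_glint_spec <- function(tau, a = 1, base_delay = 11e-3) {
  stopifnot_scalar(tau, "tau")
  if (tau <= 0) stop("`tau` must be > 0")
  stopifnot_scalar(a, "a")
  if (a < 0) stop("`a` must be >= 0")
  stopifnot_scalar(base_delay, "base_delay")
  structure(list(tau = tau, a = a, base_delay = base_delay),
            class = "two_glint_spec")
}

#' Two-glint impulse response
#'
#' Realizes `x(t) = e(t - d0) + a * e(t - d0 - tau)`; `leading_gain_db`
#' attenuates (or boosts) the leading glint, as in conditions where the
#' leading echo is set several dB below the trailing one.
#'
#' @param spec A [two_glint_spec()].
#' @param leading_gain_db Level of the leading glint in dB (default 0).
#' @return An `impulse_response` with two glints (one if `a == 0`).
#' @export
two_glint_ir <- function(spec, leading_gain_db = 0) {
  if (!inherits(spec, "two_glint_spec")) stop("`spec` must be a two_glint_spec")
  lead <- db_to_lin(leading_gain_db)
  if (spec$a == 0) return(impulse_response(spec$base_delay, lead))
  impulse_response(c(spec$base_delay, spec$base_delay + spec$tau),
                   c(lead, spec$a))
}

#' Spectral notch frequencies of a two-glint echo
#'
#' Two glints separated by `tau` interfere destructively at
#' `f = (2m + 1) / (2 tau)`, m = 0, 1, ...
#'
#' @param tau Inter-glint delay in seconds.
#' @param m_max Highest notch order to return.
#' @return Numeric vector of notch frequencies in Hz, orders 0..`m_max`.
#' @export
notch_frequencies <- function(tau, m_max = 0) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  if (!is.numeric(m_max) || length(m_max) != 1L || m_max < 0 ||
      m_max != round(m_max))
    stop("`m_max` must be a nonnegative integer")
  (2 * (0:m_max) + 1) / (2 * tau)
}

#' Inter-glint delay producing a given first notch
#'
#' Inverse of [notch_frequencies()] at order m = 0: `tau = 1 / (2 f)`.
#'
#' @param f_notch First-notch frequency in Hz.
#' @return Delay in seconds.
#' @export
tau_for_notch <- function(f_notch) {
  stopifnot_scalar(f_notch, "f_notch", positive = TRUE)
  1 / (2 * f_notch)
}

#' Random multi-glint impulse response
#'
#' Glint delays are uniform over `[base_delay, base_delay + span]` and
#' amplitudes uniform over `amp_range`, mimicking complex stochastic
#' reflectors used in scale-discrimination experiments.
#'
#' @param n_glints Number of glints (>= 1).
#' @param span Width of the delay interval in seconds.
#' @param base_delay Start of the delay interval in seconds.
#' @param amp_range Length-2 range of uniform amplitudes.
#' @param seed Optional RNG seed for reproducibility.
#' @return An `impulse_response`.
#' @export
random_ir <- function(n_glints, span, base_delay = 11e-3,
                      amp_range = c(0.25, 1), seed = NULL) {
  if (!is.numeric(n_glints) || n_glints < 1) stop("`n_glints` must be >= 1")
  stopifnot_scalar(span, "span", positive = TRUE)
  with_rng_seed(seed, {
    d <- base_delay + stats::runif(n_glints, 0, span)
    a <- stats::runif(n_glints, amp_range[1], amp_range[2])
    impulse_response(d, a)
  })
}

#' Scale an impulse response (reflector size change)
#'
#' Time-axis scaling about the leading glint: relative delays are multiplied
#' by `s`, amplitudes by `s^2` (reflective area grows with the square of the
#' linear scale).
#'
#' @param ir An `impulse_response`.
#' @param s Scale factor (> 0).
#' @return A scaled `impulse_response`.
#' @export
scale_ir <- function(ir, s) {
  if (!inherits(ir, "impulse_response")) stop("`ir` must be an impulse_response")
  stopifnot_scalar(s, "s", positive = TRUE)
  d0 <- ir$delays[1L]
  d <- d0 + (ir$delays - d0) * s
  win <- WINDOW_N / DEFAULT_FS
  if (any(d >= win))
    stop("scaled glint delays exceed the analysis window")
  impulse_response(d, ir$amplitudes * s^2, allow_negative = TRUE)
}

# Band-limited synthesis of sum_g a_g * e(t - d_g) on the analysis window.
# Delays are applied as exact phase ramps in the frequency domain.
#' @keywords internal
sparse_conv <- function(emission, delays, amplitudes, n_out) {
  fs <- emission$fs
  nfft <- next_pow2(n_out + length(emission$samples) + 64L)
  E <- stats::fft(c(emission$samples, numeric(nfft - length(emission$samples))))
  f <- (seq_len(nfft) - 1L) / nfft * fs
  # use signed frequencies so the phase ramp is conjugate-symmetric
  f[f > fs / 2] <- f[f > fs / 2] - fs
  H <- 0
  for (g in seq_along(delays))
    H <- H + amplitudes[g] * exp(-2i * pi * f * delays[g])
  x <- Re(stats::fft(E * H, inverse = TRUE)) / nfft
  x[seq_len(n_out)]
}

#' Synthesize a phantom echo
#'
#' Convolves the emission with a sparse impulse response into the fixed
#' analysis window, with optional amplitude roving: the overall level (or
#' each glint's level with `rove_mode = "per_glint"`) is multiplied by
#' `10^(u/20)` with `u` uniform on `[-rove_db/2, +rove_db/2]`.
#'
#' Fractional glint delays are honored exactly (band-limited synthesis).
#'
#' @param ir An `impulse_response`.
#' @param emission An `echo_wave` holding the emission call.
#' @param rove_db Total roving range in dB (0 disables roving).
#' @param rove_mode `"joint"` roves the whole echo, `"per_glint"` roves each
#'   glint independently.
#' @param seed Optional RNG seed.
#' @return An `echo_wave` of [window_samples()] samples.
#' @export
synthesize_echo <- function(ir, emission, rove_db = 0,
                            rove_mode = c("joint", "per_glint"), seed = NULL) {
  if (!inherits(ir, "impulse_response")) stop("`ir` must be an impulse_response")
  if (!inherits(emission, "echo_wave")) stop("`emission` must be an echo_wave")
  rove_mode <- match.arg(rove_mode)
  n_out <- window_samples(emission$fs)
  with_rng_seed(seed, {
    amps <- ir$amplitudes
    if (rove_db > 0) {
      if (rove_mode == "joint") {
        amps <- amps * db_to_lin(stats::runif(1, -rove_db / 2, rove_db / 2))
      } else {
        amps <- amps * db_to_lin(stats::runif(length(amps),
                                              -rove_db / 2, rove_db / 2))
      }
    }
    x <- sparse_conv(emission, ir$delays, amps, n_out)
    echo_wave(x, fs = emission$fs, t0 = 0)
  })
}
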