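# Parametric stand-in for a measured head-related transfer function.
#
# Real bat HRTFs place an elevation-dependent spectral notch in the sonar
# band; the toy set reproduces just that monaural cue: per elevation a
# linear-phase FIR that is flat except for a Gaussian-shaped dip (in dB)
# whose center frequency moves linearly with elevation.

#' Construct a toy elevation-notch HRTF set
#'
#' @param notch_at_zero Notch center frequency at 0 degrees elevation (Hz).
#' @param notch_slope Notch movement in Hz per degree of elevation.
#' @param depth_db Notch depth in dB (0 gives an all-pass set).
#' @param grid Elevation grid in degrees (must cover at least -20..20).
#' @param notch_width Gaussian notch width (std dev) in Hz.
#' @param fs Sample rate in Hz.
#' @param n_taps FIR length in samples (even).
#' @param band Frequency band (Hz) the notch must stay inside across the
#'   grid. Defaults to the emission sweep band: a notch outside it is
#'   inaudible through the system, which would make extreme elevations
#'   untestable rather than easy.
#' @return An object of class `hrtf_set` with one FIR filter per elevation.
#' @export
make_toy_hrtf <- function(notch_at_zero = 50000, notch_slope = 500,
                          depth_db = 25, grid = seq(-20, 20, by = 1),
                          notch_width = 2000, fs = DEFAULT_FS, n_taps = 512L,
                          band = c(30000, 70000)) {
  stopifnot_scalar(notch_at_zero, "notch_at_zero", positive = TRUE)
  stopifnot_scalar(notch_slope, "notch_slope")
  stopifnot_scalar(depth_db, "depth_db")
  if (depth_db < 0) stop("`depth_db` must be >= 0")
  if (min(grid) > -20 || max(grid) < 20)
    stop("elevation grid must cover at least -20..+20 degrees")
  notches <- notch_at_zero + notch_slope * grid
  if (depth_db > 0 && (any(notches < band[1]) || any(notches > band[2])))
    stop(sprintf("notch leaves the %g-%g kHz band across the elevation grid",
                 band[1] / 1000, band[2] / 1000))
  n_taps <- as.integer(n_taps)
  half <- n_taps %/% 2L
  f <- (0:half) / n_taps * fs                     # one-sided frequency grid
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n_taps - 1L)) / (n_taps - 1L))
  filters <- lapply(notches, function(fn) {
    mag_db <- -depth_db * exp(-((f - fn)^2) / (2 * notch_width^2))
    mag <- db_to_lin(mag_db)
    full <- c(mag, rev(mag[2:half]))              # conjugate-symmetric, real
    h <- Re(stats::fft(full, inverse = TRUE)) / n_taps
    h <- c(h[(half + 1L):n_taps], h[1:half])      # linear phase, causal
    h * win
  })
  structure(list(elevations = as.numeric(grid), filters = filters,
                 fs = fs, n_taps = n_taps, delay_samples = half,
                 notch_freqs = notches, depth_db = depth_db,
                 provenance = "toy"),
            class = "hrtf_set")
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat(sprintf("<hrtf_set> %s, %d elevations (%g..%g deg), %d-tap FIRs\n",
              x$provenance, length(x$elevations), min(x$elevations),
              max(x$elevations), x$n_taps))
  invisible(x)
}

#' Filter an echo through the HRTF at a given elevation
#'
#' Selects the nearest elevation on the grid (the elevation must lie within
#' the grid range) and convolves the echo with that filter. The filters'
#' common linear-phase group delay is compensated, so an all-pass set leaves
#' the echo unchanged.
#'
#' @param echo An `echo_wave`.
#' @param elevation Elevation in degrees.
#' @param hrtf An `hrtf_set`.
#' @return The filtered `echo_wave`, same length as the input.
#' @export
apply_hrtf <- function(echo, elevation, hrtf) {
  if (!inherits(echo, "echo_wave")) stop("`echo` must be an echo_wave")
  if (!inherits(hrtf, "hrtf_set")) stop("`hrtf` must be an hrtf_set")
  stopifnot_scalar(elevation, "elevation")
  if (elevation < min(hrtf$elevations) || elevation > max(hrtf$elevations))
    stop(sprintf("elevation %g deg is outside the HRTF grid (%g..%g)",
                 elevation, min(hrtf$elevations), max(hrtf$elevations)))
  if (echo$fs != hrtf$fs) stop("echo and HRTF sample rates differ")
  k <- which.min(abs(hrtf$elevations - elevation))
  h <- hrtf$filters[[k]]
  n <- length(echo$samples)
  nfft <- next_pow2(n + length(h))
  X <- stats::fft(c(echo$samples, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y <- y[hrtf$delay_samples + seq_len(n)]         # undo linear-phase delay
  echo_wave(y, fs = echo$fs, t0 = echo$t0)
}
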