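# Compressive linear encoding of cochleograms: mean removal, PCA to 25
# dimensions, then a FastICA rotation within the retained subspace, so that
# a cochleogram x is represented as x = mean + A c with 25 maximally
# independent weights c. The 25 basis columns play the role of
# spectrotemporal receptive fields.

#' Fit the compressive PCA+ICA encoding basis
#'
#' Removes the mean cochleogram, projects onto the top `n_components`
#' principal components, and rotates within that subspace with symmetric
#' FastICA (logcosh contrast) to minimize statistical dependence of the
#' weights. PCA is computed from the observation Gram matrix, so the number
#' of observations — not the 140000-sample dimension — sets the cost.
#'
#' @param x A list of `cochleogram`s (all the same shape) or a numeric matrix
#'   with one flattened observation per row (columns of the cochleogram
#'   concatenated).
#' @param n_components Number of retained components (default 25).
#' @param seed RNG seed for the ICA initialization.
#' @param max_iter,tol FastICA iteration cap and convergence tolerance.
#' @return An object of class `encoding_basis` with fields `mean`,
#'   `components` (orthonormal PCA directions, columns), `sdev`,
#'   `explained_variance_ratio`, `ica_w` (orthogonal rotation) and metadata
#'   for reshaping decoded cochleograms.
#' @export
fit_basis <- function(x, n_components = 25L, seed = 1L,
                      max_iter = 500L, tol = 1e-4) {
  meta <- NULL
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    if (!all(vapply(x, inherits, logical(1), "cochleogram")))
      stop("`x` must be a list of cochleograms or a numeric matrix")
    d <- dim(x[[1]]$values)
    meta <- list(dim = d, spec = x[[1]]$spec, dechirped = x[[1]]$dechirped)
    X <- t(vapply(x, function(cc) {
      if (!identical(dim(cc$values), d)) stop("cochleogram shapes differ")
      as.vector(cc$values)
    }, numeric(prod(d))))
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  k <- as.integer(n_components)
  if (n <= k)
    stop(sprintf("need more than %d observations to fit %d components", k, k))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  G <- tcrossprod(Xc)                       # n x n Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  total <- sum(lam)
  if (lam[k] <= total * 1e-12)
    stop("ensemble is rank deficient: fewer than `n_components` directions of variance")
  s <- sqrt(lam[1:k])
  U <- eg$vectors[, 1:k, drop = FALSE]
  V <- crossprod(Xc, U)                      # p x k
  V <- sweep(V, 2L, s, "/")                  # orthonormal PCA directions
  sdev <- s / sqrt(n - 1)
  evr <- lam[1:k] / total
  Z <- U * sqrt(n - 1)                       # whitened scores, n x k
  ica <- fastica_symmetric(Z, seed = seed, max_iter = max_iter, tol = tol)
  structure(list(mean = mu, components = V, sdev = sdev,
                 explained_variance_ratio = evr, total_variance = total / (n - 1),
                 ica_w = ica$w, ica_converged = ica$converged,
                 ica_iterations = ica$iterations,
                 n_components = k, n_obs = n, seed = seed, meta = meta),
            class = "encoding_basis")
}

#' @export
print.encoding_basis <- function(x, ...) {
  cat(sprintf(paste0("<encoding_basis> %d components over %d-dim observations",
                     " (n = %d)\n  top-%d PCA variance: %.2f %%; ICA %s in %d",
                     " iterations\n"),
              x$n_components, length(x$mean), x$n_obs, x$n_components,
              100 * sum(x$explained_variance_ratio),
              if (x$ica_converged) "converged" else "did not converge",
              x$ica_iterations))
  invisible(x)
}

# Symmetric FastICA with the logcosh contrast on pre-whitened data.
# Z: n x k, unit-variance uncorrelated columns. Returns the orthogonal
# unmixing rotation W (rows are units): sources = Z %*% t(W).
#' @keywords internal
fastica_symmetric <- function(Z, seed = 1L, max_iter = 500L, tol = 1e-4) {
  n <- nrow(Z); k <- ncol(Z)
  W <- with_rng_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% W
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    S <- Z %*% t(W)
    G <- tanh(S)
    gprime <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - gprime * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(w = W, converged = converged, iterations = it)
}

# flatten cochleogram / matrix / vector input for encode()
#' @keywords internal
as_obs_matrix <- function(x, basis) {
  p <- length(basis$mean)
  if (inherits(x, "cochleogram")) x <- matrix(as.vector(x$values), nrow = 1L)
  else if (is.list(x) && !is.matrix(x))
    x <- t(vapply(x, function(cc) as.vector(cc$values), numeric(p)))
  else if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  else x <- as.matrix(x)
  if (ncol(x) != p)
    stop(sprintf("observation length %d does not match the basis dimension %d",
                 ncol(x), p))
  x
}

#' Unmixing map of an encoding basis
#'
#' The `n_components x p` linear map taking a centered observation to its
#' code: `c = W diag(1/sdev) V' (x - mean)`.
#'
#' @param basis An `encoding_basis`.
#' @return A dense matrix.
#' @export
unmixing_matrix <- function(basis) {
  basis$ica_w %*% (t(basis$components) / basis$sdev)
}

#' Mixing matrix (basis columns)
#'
#' The `p x n_components` matrix `A` with the basis functions as columns:
#' `x_hat = mean + A c`.
#'
#' @param basis An `encoding_basis`.
#' @return A dense matrix.
#' @export
mixing_matrix <- function(basis) {
  (basis$components * rep(basis$sdev, each = nrow(basis$components))) %*%
    t(basis$ica_w)
}

#' Encode cochleograms into 25-dimensional codes
#'
#' @param x A `cochleogram`, a list of them, or a numeric matrix/vector of
#'   flattened observations.
#' @param basis An `encoding_basis`.
#' @return A numeric matrix with one code (length `n_components`) per row;
#'   a single input gives a one-row matrix.
#' @export
encode <- function(x, basis) {
  if (!inherits(basis, "encoding_basis")) stop("`basis` must be an encoding_basis")
  X <- as_obs_matrix(x, basis)
  Z <- sweep(X %*% basis$components, 2L,
             colSums(basis$components * basis$mean)) # (x - mean)' V
  Z <- sweep(Z, 2L, basis$sdev, "/")
  Z %*% t(basis$ica_w)
}

#' Decode codes back to cochleograms
#'
#' `x_hat = mean + A c`; by construction `decode(encode(x))` equals the
#' rank-`n_components` PCA reconstruction of `x`.
#'
#' @param code A code vector or matrix of codes (one per row).
#' @param basis An `encoding_basis`.
#' @return If the basis was fitted on cochleograms and a single code is
#'   given, a reconstructed `cochleogram` (values may be slightly negative);
#'   otherwise a matrix of flattened reconstructions.
#' @export
decode <- function(code, basis) {
  if (!inherits(basis, "encoding_basis")) stop("`basis` must be an encoding_basis")
  C <- if (is.null(dim(code))) matrix(code, nrow = 1L) else as.matrix(code)
  if (ncol(C) != basis$n_components)
    stop(sprintf("codes must have length %d", basis$n_components))
  S <- sweep(C %*% basis$ica_w, 2L, basis$sdev, "*")
  Xh <- sweep(S %*% t(basis$components), 2L, basis$mean, "+")
  if (nrow(Xh) == 1L && !is.null(basis$meta)) {
    vals <- matrix(Xh[1L, ], nrow = basis$meta$dim[1], ncol = basis$meta$dim[2])
    return(new_cochleogram(vals, basis$meta$spec,
                           dechirped = basis$meta$dechirped,
                           reconstructed = TRUE))
  }
  Xh
}

#' A component as a unit-norm spectrotemporal field
#'
#' Reshapes column `i` of the mixing matrix back to the cochleogram layout
#' (channels x time), normalized to unit Euclidean norm.
#'
#' @param basis An `encoding_basis` fitted on cochleograms.
#' @param i Component index (1-based).
#' @return A channels-by-time numeric matrix.
#' @export
component_field <- function(basis, i) {
  if (i < 1L || i > basis$n_components) stop("component index out of range")
  if (is.null(basis$meta))
    stop("basis was not fitted on cochleograms; no spectrotemporal layout")
  psi <- mixing_matrix(basis)[, i]
  psi <- psi / sqrt(sum(psi^2))
  matrix(psi, nrow = basis$meta$dim[1], ncol = basis$meta$dim[2])
}

#' Spectral profile of a component
#'
#' Time-average of the (unit-norm) component, one value per frequency
#' channel — the component's frequency response.
#'
#' @param basis An `encoding_basis` fitted on cochleograms.
#' @param i Component index (1-based).
#' @return Numeric vector, one value per channel.
#' @export
spectral_profile <- function(basis, i) rowMeans(component_field(basis, i))

#' Temporal profile of a component
#'
#' Frequency-average of the (unit-norm) component, one value per time sample
#' — the component's delay (distance) response.
#'
#' @inheritParams spectral_profile
#' @return Numeric vector, one value per time sample.
#' @export
temporal_profile <- function(basis, i) colMeans(component_field(basis, i))

#' Best delay of a component
#'
#' The time at which the absolute temporal profile peaks; ties are broken
#' toward the earlier delay.
#'
#' @inheritParams spectral_profile
#' @return Delay in seconds.
#' @export
best_delay <- function(basis, i) {
  tp <- abs(temporal_profile(basis, i))
  (which.max(tp) - 1L) / basis$meta$spec$fs
}

#' Temporal response width of a component
#'
#' Full width at half maximum of the absolute temporal profile around the
#' best delay (sides that never fall below half-height extend to the window
#' edge).
#'
#' @inheritParams spectral_profile
#' @return Width in seconds.
#' @export
response_width <- function(basis, i) {
  tp <- abs(temporal_profile(basis, i))
  pk <- which.max(tp)
  half <- tp[pk] / 2
  lo <- pk
  while (lo > 1L && tp[lo - 1L] >= half) lo <- lo - 1L
  hi <- pk
  while (hi < length(tp) && tp[hi + 1L] >= half) hi <- hi + 1L
  (hi - lo + 1L) / basis$meta$spec$fs
}

#' Histogram of component best delays
#'
#' @param basis An `encoding_basis` fitted on cochleograms.
#' @param breaks Passed to [graphics::hist()]'s binning (computed without
#'   plotting).
#' @return A list with the per-component `delays` (seconds) and the `hist`
#'   object over them.
#' @export
best_delay_histogram <- function(basis, breaks = "Sturges") {
  d <- vapply(seq_len(basis$n_components), function(i) best_delay(basis, i),
              numeric(1))
  list(delays = d, hist = graphics::hist(d, breaks = breaks, plot = FALSE))
}
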