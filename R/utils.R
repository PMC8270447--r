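# internal helpers shared across modules

#' Decibel / linear amplitude conversions
#'
#' `db_to_lin(db) = 10^(db/20)` and its inverse; amplitude (20 log10)
#' convention throughout the package.
#'
#' @param db Level in dB.
#' @param lin Linear amplitude ratio (> 0).
#' @return The converted value.
#' @export
db_to_lin <- function(db) 10^(db / 20)

#' @rdname db_to_lin
#' @export
lin_to_db <- function(lin) 20 * log10(lin)

# Run `code` under a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws from it).
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
#' @keywords internal
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483587)
}

#' @keywords internal
stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# smallest power of two >= n
#' @keywords internal
next_pow2 <- function(n) 2^ceiling(log2(n))
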