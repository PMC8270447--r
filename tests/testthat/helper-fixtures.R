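# Shared fixtures, built once per test run and memoized.

fb_default <- filterbank_spec()
em_spec_default <- emission_spec()
em_default <- make_emission()

# A small but complete synthetic campaign: 8 locations (two sibling pairs),
# 8 poses x 3 repeats each -> 64 averaged cochleograms, enough to fit a
# 25-component basis.
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      locs <- default_location_specs(n_locations = 8L, n_indoor = 4L,
                                     n_sibling_pairs = 2L, seed = 101L)
      ds <- generate_dataset(locations = locs,
                             poses_per_location = rep(8L, 8L), seed = 101L)
      ens <- ensemble_cochleograms(ds)
      gain <- normalize_reference_level(ens$cochs)
      ens$cochs <- lapply(ens$cochs, sonocode:::scale_cochleogram, gain)
      basis <- fit_basis(ens$cochs, 25L, seed = 5L)
      cache <<- list(locs = locs, ds = ds, ens = ens, gain = gain,
                     basis = basis)
    }
    cache
  }
})

# reference-level and internal-noise calibration shared across tests
tiny_noise <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref_gain <- calibrate_reference_gain()
      nm <- calibrate_internal_noise(ref_gain, n_mc = 20000L, seed = 3L)
      cache <<- list(ref_gain = ref_gain, noise = nm)
    }
    cache
  }
})

# greedy column matching by maximal absolute cosine (handles ICA sign and
# permutation indeterminacy)
match_abs_cosine <- function(A, B) {
  cn <- function(M) sweep(M, 2L, sqrt(colSums(M^2)), "/")
  C <- abs(crossprod(cn(A), cn(B)))
  apply(C, 2L, max)
}
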