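test_that("the basis captures constructed low-rank structure completely", {
  set.seed(10)
  p <- 120L; n <- 60L
  U <- qr.Q(qr(matrix(rnorm(p * 25L), p)))[, 1:25]
  X <- matrix(rnorm(n * 25L), n) %*% t(U)  # exactly rank 25 about mean 0
  b <- fit_basis(X, 25L, seed = 2L)
  expect_gt(sum(b$explained_variance_ratio), 1 - 1e-8)
  expect_true(all(diff(b$explained_variance_ratio) <= 1e-12))
  # components orthonormal
  G <- crossprod(b$components)
  expect_lt(max(abs(G - diag(25L))), 1e-8)
})

test_that("decode(encode(x)) equals the rank-25 PCA reconstruction", {
  set.seed(11)
  n <- 80L; p <- 200L
  X <- matrix(rnorm(n * p), n) %*% diag(seq(3, 0.1, length.out = p))
  b <- fit_basis(X, 25L, seed = 3L)
  C <- encode(X, b)
  Xh <- decode(C, b)
  # independent oracle: centered SVD truncated at 25 components
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 25L, nv = 25L)
  Xh_oracle <- sweep(sv$u %*% (sv$d[1:25] * t(sv$v)), 2L, mu, "+")
  expect_lt(max(abs(Xh - Xh_oracle)), 1e-8)
  # residual variance matches the unexplained-variance bookkeeping
  resid <- sum((Xc - sweep(Xh, 2L, mu))^2) / (n - 1)
  expect_equal(resid, (1 - sum(b$explained_variance_ratio)) * b$total_variance,
               tolerance = 1e-8)
  # mean maps to the zero code and back
  expect_lt(max(abs(encode(mu, b))), 1e-8)
  expect_equal(as.vector(decode(matrix(0, 1, 25), b)), mu, tolerance = 1e-10)
})

test_that("codes respond one-for-one to their own mixing column", {
  set.seed(12)
  X <- matrix(rnorm(60L * 150L), 60L)
  b <- fit_basis(X, 25L, seed = 4L)
  A <- mixing_matrix(b)
  x0 <- X[1, ]
  c0 <- encode(x0, b)
  for (i in c(1L, 13L, 25L)) {
    ci <- encode(x0 + A[, i], b)
    delta <- as.vector(ci - c0)
    expect_equal(delta[i], 1, tolerance = 1e-8)
    expect_lt(max(abs(delta[-i])), 1e-8)
  }
  # unmixing and mixing are mutually inverse on the code space
  W <- unmixing_matrix(b)
  expect_lt(max(abs(W %*% A - diag(25L))), 1e-8)
})

test_that("ICA recovers independent non-Gaussian sources", {
  set.seed(13)
  n <- 2000L; k <- 25L; p <- 60L
  S <- matrix(rexp(n * k) * sample(c(-1, 1), n * k, TRUE), n)  # Laplace
  M <- matrix(rnorm(p * k), p)
  X <- S %*% t(M)
  b <- fit_basis(X, k, seed = 6L)
  best <- match_abs_cosine(mixing_matrix(b), M)
  expect_true(all(best > 0.95))
})

test_that("ICA rotation preserves the principal subspace", {
  set.seed(14)
  X <- matrix(rnorm(70L * 300L), 70L)
  b <- fit_basis(X, 25L, seed = 7L)
  # W is orthogonal
  expect_lt(max(abs(tcrossprod(b$ica_w) - diag(25L))), 1e-8)
  # span(mixing columns) == span(principal components)
  A <- mixing_matrix(b)
  P <- b$components %*% crossprod(b$components, A)  # project A onto span(V)
  expect_lt(max(abs(P - A)) / max(abs(A)), 1e-8)
})

test_that("fitting rejects ensembles too small for the requested rank", {
  X <- matrix(rnorm(10L * 50L), 10L)
  expect_error(fit_basis(X, 25L), "rank|observations")
})

test_that("component fields expose spectral and temporal structure", {
  w <- tiny_world()
  b <- w$basis
  f <- component_field(b, 1L)
  expect_equal(dim(f), c(20L, 7000L))
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-9)
  sp <- spectral_profile(b, 1L)
  tp <- temporal_profile(b, 1L)
  expect_equal(length(sp), 20L)
  expect_equal(length(tp), 7000L)
  bd <- vapply(1:25, function(i) best_delay(b, i), numeric(1))
  expect_true(all(bd >= 0 & bd < 7000 / fb_default$fs))
  rw <- vapply(1:25, function(i) response_width(b, i), numeric(1))
  expect_true(all(rw > 0))
  h <- best_delay_histogram(b)
  expect_equal(length(h$delays), 25L)
  expect_equal(sum(h$hist$counts), 25L)
})
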