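`%||%` <- function(a, b) if (is.null(a)) b else a

# Cholesky-based MVN sampler; accepts PSD matrices (eigen fallback when chol
# fails on a boundary covariance such as a zero growth-residual matrix).
rmvn <- function(n, mean, sigma) {
  p <- length(mean)
  if (all(sigma == 0)) {
    return(matrix(rep(mean, each = n), n, p))
  }
  L <- tryCatch(t(chol(sigma)), error = function(e) {
    e <- eigen(sigma, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  })
  z <- matrix(stats::rnorm(n * p), p, n)
  t(L %*% z + mean)
}

# deterministic per-stage seed derivation (kept well below .Machine$integer.max)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97L + k * 1009L) %% 2147483629)
}
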