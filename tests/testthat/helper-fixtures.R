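# Shared fixtures, built in code at test time.

# A 3D array wrapped from a matrix (single slice).
as_vol <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

full_mask <- function(dims) array(TRUE, dim = dims)

# Random quantized volume with a random-but-nonempty mask, for oracle checks.
random_quantized <- function(dims = c(8, 8, 8), levels = 4L,
                             mask_prob = 0.8) {
  q <- array(sample(0:(levels - 1L), prod(dims), replace = TRUE), dim = dims)
  m <- array(stats::runif(prod(dims)) < mask_prob, dim = dims)
  while (sum(m) < 2) m <- array(stats::runif(prod(dims)) < mask_prob,
                                dim = dims)
  q[!m] <- NA_integer_
  q
}

# Naive double-loop GLCM oracle: enumerate every voxel, apply the offset,
# count pairs with both endpoints in-mask. Independent of compute_glcm.
glcm_oracle <- function(q, spec) {
  d <- dim(q)
  L <- spec$levels
  o <- spec$direction * spec$distance
  cnt <- matrix(0L, L, L)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    i2 <- i + o[1]; j2 <- j + o[2]; k2 <- k + o[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3])
      next
    a <- q[i, j, k]; b <- q[i2, j2, k2]
    if (is.na(a) || is.na(b)) next
    cnt[a + 1L, b + 1L] <- cnt[a + 1L, b + 1L] + 1L
  }
  if (spec$symmetric) cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

# Small two-class score set with ties exercised.
random_scores <- function(n1 = 12, n0 = 9, ties = TRUE) {
  s <- if (ties) sample(1:6, n1 + n0, replace = TRUE) + 0
       else stats::rnorm(n1 + n0)
  list(scores = s, labels = c(rep(1L, n1), rep(0L, n0)))
}

# Negative Bernoulli log-likelihood and gradient on a fixed design,
# for the independent-optimizer logistic oracle.
neg_loglik <- function(X, y) {
  function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
}
neg_score <- function(X, y) {
  function(b) -drop(crossprod(X, y - stats::plogis(drop(X %*% b))))
}
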