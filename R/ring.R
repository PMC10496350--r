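# Ring-element helpers for the toy RLWE backend. A ring element is an
# n x L numeric matrix of residues (one column per CRT prime); residues stay
# below 2^50 so double arithmetic on them is exact.

ring_zero <- function(params) {
  matrix(0, params$poly_degree, length(params$primes))
}

# reduce a signed integer-valued vector/matrix into residue columns; the
# reduction runs through exact fmod in C++ because encode coefficients can
# exceed the magnitude where R's `%%` on doubles stays exact
ring_from_int <- function(x, params) {
  mod_reduce_cpp(as.vector(x), params$primes)
}

ring_add <- function(a, b, params) {
  s <- a + b
  for (l in seq_along(params$primes)) s[, l] <- s[, l] %% params$primes[l]
  s
}

ring_sub <- function(a, b, params) {
  s <- a - b
  for (l in seq_along(params$primes)) s[, l] <- s[, l] %% params$primes[l]
  s
}

ring_neg <- function(a, params) {
  s <- -a
  for (l in seq_along(params$primes)) s[, l] <- s[, l] %% params$primes[l]
  s
}

ring_mul <- function(a, b, params) {
  poly_mul_cpp(a, b, params$primes)
}

# multiply by 2^k via k exact doublings (k can be large; each step is exact)
ring_scale_pow2 <- function(a, k, params) {
  stopifnot(k >= 0, k == round(k))
  for (i in seq_len(k)) {
    a <- 2 * a
    for (l in seq_along(params$primes)) a[, l] <- a[, l] %% params$primes[l]
  }
  a
}

# centered lift to signed doubles in (-q/2, q/2]
ring_center <- function(a, params) {
  crt_center_cpp(a, params$primes)
}

# Galois automorphism x -> x^g on coefficients (negacyclic sign rule)
ring_automorph <- function(a, g, params) {
  n <- params$poly_degree
  k <- 0:(n - 1)
  m <- (k * g) %% (2 * n)
  wrap <- m >= n
  idx <- ifelse(wrap, m - n, m) + 1
  out <- matrix(0, n, ncol(a))
  for (l in seq_len(ncol(a))) {
    col <- numeric(n)
    col[idx] <- ifelse(wrap, -a[k + 1, l], a[k + 1, l])
    out[, l] <- col %% params$primes[l]
  }
  out
}

# samplers ------------------------------------------------------------------

ring_sample_ternary <- function(params) {
  x <- sample(c(-1, 0, 1), params$poly_degree, replace = TRUE)
  list(int = x, res = ring_from_int(x, params))
}

ring_sample_gaussian <- function(params, sd) {
  x <- round(rnorm(params$poly_degree, 0, sd))
  ring_from_int(x, params)
}

ring_sample_uniform <- function(params) {
  n <- params$poly_degree
  out <- matrix(0, n, length(params$primes))
  for (l in seq_along(params$primes)) {
    p <- params$primes[l]
    # two 25-bit draws give a 50-bit uniform value; mod bias is negligible
    out[, l] <- (floor(runif(n, 0, 2^25)) * 2^25 + floor(runif(n, 0, 2^25))) %% p
  }
  out
}
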