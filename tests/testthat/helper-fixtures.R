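# Shared fixtures: small key bundles are expensive enough to build once.

toy_params64 <- fedhegwas:::toy_test_params(n = 64, n_sites = 3)
toy_bundle64 <- make_key_bundle(toy_params64, seed = 42, keep_master = TRUE)

em_params64 <- he_params(poly_degree = 64, n_sites = 3, backend = "emulated")
em_bundle64 <- make_key_bundle(em_params64, seed = 42, keep_master = TRUE)

# high-precision toy parameters for threshold-decryption checks: the decoded
# smudging error is ~ sqrt(n * S) * 2^(sm/2) / scale, so scale 2^35 keeps the
# default 40-bit smudging below 1e-2 at n = 64
toy_params_hp <- fedhegwas:::toy_test_params(n = 64, n_sites = 3,
                                             scale_bits = 35,
                                             coeff_modulus_bits = c(50, 50))
toy_bundle_hp <- make_key_bundle(toy_params_hp, seed = 43, keep_master = TRUE)

backend_fixtures <- list(
  toy_ckks = list(params = toy_params64, bundle = toy_bundle64),
  emulated = list(params = em_params64, bundle = em_bundle64)
)

open_shares <- function(bundle) {
  lapply(seq_len(bundle$n_sites), function(s) open_key_bundle(bundle, s)$share)
}

# threshold decryption helper (one partial per site, site 1 contributes c0)
threshold_decrypt <- function(ct, bundle, params, seed = 7) {
  shares <- open_shares(bundle)
  partials <- lapply(seq_along(shares), function(s) {
    partial_decrypt(ct, shares[[s]], params, include_c0 = s == 1,
                    seed = seed + s)
  })
  aggregate_partials(partials, params)$slots
}

# deterministic small cohort generator for GWAS unit tests
tiny_cohort <- function(n = 60, p = 3, m = 8, seed = 1, beta = NULL) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  eta <- if (is.null(beta)) rnorm(n, 0, 0.5) else drop(G %*% beta) + rnorm(n, 0, 0.5)
  y <- as.numeric(plogis(eta) > runif(n))
  site_cohort(X, y, G)
}

make_sites <- function(bundle, seed = 500) {
  lapply(seq_len(bundle$n_sites), function(s)
    site_context(s, bundle, seed = seed + s))
}
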