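# ToyCKKS: a real single-modulus RLWE/CKKS scheme at small ring degree.
# Encoding is the inverse canonical embedding; multiplication relinearizes
# with a digit-decomposed key-switching key; rotations use Galois
# automorphisms along the orbit of 5 with per-power-of-two rotation keys.

toy_encrypt <- function(pt, pk, params) {
  m <- encode_to_ring(pt, params)
  v <- ring_sample_ternary(params)$res
  e0 <- ring_sample_gaussian(params, params$err_sd)
  e1 <- ring_sample_gaussian(params, params$err_sd)
  c0 <- ring_add(ring_add(ring_mul(v, pk$pk0, params), m, params), e0, params)
  c1 <- ring_add(ring_mul(v, pk$pk1, params), e1, params)
  new_ciphertext("toy_ckks", list(c0 = c0, c1 = c1, params = params),
                 level = params$max_level, scale = pt$scale,
                 n_slots = params$slot_size)
}

ct_params <- function(a) a$payload$params

toy_add <- function(a, b) {
  params <- ct_params(a)
  a$payload$c0 <- ring_add(a$payload$c0, b$payload$c0, params)
  a$payload$c1 <- ring_add(a$payload$c1, b$payload$c1, params)
  a
}

toy_sub <- function(a, b) {
  params <- ct_params(a)
  a$payload$c0 <- ring_sub(a$payload$c0, b$payload$c0, params)
  a$payload$c1 <- ring_sub(a$payload$c1, b$payload$c1, params)
  a
}

ks_apply <- function(d, ksk, params) {
  digs <- digit_decompose_cpp(d, params$primes, params$ks_base_bits,
                              params$ks_ndigits)
  k0 <- ring_zero(params)
  k1 <- ring_zero(params)
  for (i in seq_along(digs)) {
    k0 <- ring_add(k0, ring_mul(digs[[i]], ksk[[i]]$k0, params), params)
    k1 <- ring_add(k1, ring_mul(digs[[i]], ksk[[i]]$k1, params), params)
  }
  list(k0 = k0, k1 = k1)
}

toy_mul <- function(a, b, evk, params) {
  if (is.null(evk$relin)) stop("capability error: no relinearization key")
  d0 <- ring_mul(a$payload$c0, b$payload$c0, params)
  d1 <- ring_add(ring_mul(a$payload$c0, b$payload$c1, params),
                 ring_mul(a$payload$c1, b$payload$c0, params), params)
  d2 <- ring_mul(a$payload$c1, b$payload$c1, params)
  ks <- ks_apply(d2, evk$relin, params)
  a$payload$c0 <- ring_add(d0, ks$k0, params)
  a$payload$c1 <- ring_add(d1, ks$k1, params)
  a$level <- a$level - 1
  a$scale <- a$scale * b$scale
  a
}

toy_mul_plain <- function(a, pt, params) {
  p <- encode_to_ring(pt, params)
  a$payload$c0 <- ring_mul(a$payload$c0, p, params)
  a$payload$c1 <- ring_mul(a$payload$c1, p, params)
  a$level <- a$level - 1
  a$scale <- a$scale * pt$scale
  a
}

toy_rotate <- function(a, t, evk, params) {
  if (is.null(evk$galois)) stop("capability error: no Galois rotation keys")
  # compose from power-of-two left rotations
  k <- 0
  while (t > 0) {
    if (t %% 2 == 1) {
      key <- evk$galois[[as.character(2^k)]]
      if (is.null(key)) stop("capability error: missing Galois key for 2^", k)
      c0r <- ring_automorph(a$payload$c0, key$g, params)
      c1r <- ring_automorph(a$payload$c1, key$g, params)
      ks <- ks_apply(c1r, key$ksk, params)
      a$payload$c0 <- ring_add(c0r, ks$k0, params)
      a$payload$c1 <- ks$k1
    }
    t <- t %/% 2
    k <- k + 1
  }
  a
}

toy_partial_decrypt <- function(ct, share, params, include_c0) {
  if (nrow(share$res) != params$poly_degree) {
    stop("key error: share ring degree does not match parameters")
  }
  pd <- ring_mul(ct$payload$c1, share$res, params)
  if (params$smudging_bits > 0) {
    e_sm <- ring_sample_gaussian(params, 2^(params$smudging_bits / 2))
    pd <- ring_add(pd, e_sm, params)
  }
  if (include_c0) pd <- ring_add(pd, ct$payload$c0, params)
  structure(list(site_id = share$site_id, payload = pd,
                 includes_c0 = include_c0, backend = "toy_ckks",
                 scale = ct$scale, n_slots = ct$n_slots),
            class = "partial_decryption")
}

toy_aggregate <- function(partials, params) {
  total <- Reduce(function(x, y) ring_add(x, y, params),
                  lapply(partials, `[[`, "payload"))
  centered <- ring_center(total, params)
  slots <- decode_from_ring(centered, partials[[1]]$scale, params)
  structure(list(slots = slots, scale = 1), class = "he_plaintext")
}
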