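# Master-key generation, additive secret sharing, public/evaluation keys and
# the key bundle (the key-dealer role, run once offline and then discarded).

#' Generate the master secret key
#'
#' A length-n ternary vector with entries drawn uniformly from \{-1, 0, 1\},
#' interpreted modulo the coefficient modulus q.
#'
#' @param params an [he_params()] object
#' @param seed integer seed; the key is a deterministic function of it
#' @return an object of class `master_secret_key`
#' @export
generate_master_key <- function(params, seed) {
  coeffs <- with_seed(seed, sample(c(-1, 0, 1), params$poly_degree, replace = TRUE))
  structure(list(coeffs = coeffs, res = ring_from_int(coeffs, params)),
            class = "master_secret_key")
}

#' Split the master secret key into additive per-site shares
#'
#' Per coefficient, one randomly chosen site receives the master-key value,
#' all non-final sites receive rounded Gaussian noise with variance
#' 2^dsk_noise_bits, and the final site receives the modular complement so
#' that the shares sum to the master key entrywise mod q.
#'
#' @param msk a `master_secret_key`
#' @param params an [he_params()] object (uses `n_sites`, `dsk_noise_bits`)
#' @param seed integer seed
#' @return list of `secret_key_share` objects, one per site
#' @export
split_secret_key <- function(msk, params, seed) {
  S <- params$n_sites
  if (S < 1) stop("parameter error: need at least one site")
  n <- params$poly_degree
  with_seed(seed, {
    fin <- sample.int(S, n, replace = TRUE)     # complement holder per coeff
    sstar <- sample.int(S, n, replace = TRUE)   # site receiving msk_j
    base <- matrix(round(rnorm(S * n, 0, 2^(params$dsk_noise_bits / 2))), S, n)
    base[cbind(fin, seq_len(n))] <- 0
    add_at <- sstar != fin
    base[cbind(sstar, seq_len(n))] <- base[cbind(sstar, seq_len(n))] +
      msk$coeffs * add_at
    base[cbind(fin, seq_len(n))] <- msk$coeffs - colSums(base)
    lapply(seq_len(S), function(s) {
      structure(list(site_id = s, coeffs = base[s, ],
                     res = ring_from_int(base[s, ], params)),
                class = "secret_key_share")
    })
  })
}

#' Generate the common public key
#'
#' `(pk0, pk1) = (-a * msk + e, a) mod q` with `a` uniform over the ring and
#' `e` a small rounded Gaussian; `*` is negacyclic ring multiplication.
#'
#' @param msk a `master_secret_key`
#' @param params an [he_params()] object
#' @param seed integer seed
#' @param err_sd standard deviation of the error polynomial (0 allowed, for
#'   the noiseless identity check)
#' @return an object of class `he_public_key` with ring elements pk0, pk1
#' @export
generate_public_key <- function(msk, params, seed, err_sd = params$err_sd) {
  with_seed(seed, {
    a <- ring_sample_uniform(params)
    e <- if (err_sd > 0) ring_sample_gaussian(params, err_sd) else ring_zero(params)
    pk0 <- ring_add(ring_neg(ring_mul(a, msk$res, params), params), e, params)
    structure(list(pk0 = pk0, pk1 = a), class = "he_public_key")
  })
}

# key-switching key from secret s_from to secret s (both residue polys):
# per digit i, (ksk0_i, ksk1_i) = (-a_i*s + e_i + B^i * s_from, a_i)
make_kswitch_key <- function(s_from, s_res, params) {
  w <- params$ks_base_bits
  lapply(seq_len(params$ks_ndigits), function(i) {
    a <- ring_sample_uniform(params)
    e <- ring_sample_gaussian(params, params$err_sd)
    shifted <- ring_scale_pow2(s_from, w * (i - 1), params)
    k0 <- ring_add(ring_add(ring_neg(ring_mul(a, s_res, params), params), e, params),
                   shifted, params)
    list(k0 = k0, k1 = a)
  })
}

# relinearization (s^2 -> s) and Galois keys for left rotations by powers of
# two; arbitrary rotation amounts are composed from these
make_eval_keys <- function(msk, params, seed) {
  if (params$backend != "toy_ckks") {
    return(structure(list(backend = params$backend), class = "he_eval_keys"))
  }
  with_seed(seed, {
    s <- msk$res
    relin <- make_kswitch_key(ring_mul(s, s, params), s, params)
    n2 <- 2 * params$poly_degree
    galois <- list()
    t <- 1
    while (t < params$slot_size) {
      g <- 1
      for (i in seq_len(t)) g <- (g * 5) %% n2   # g = 5^t mod 2n
      galois[[as.character(t)]] <- list(
        g = g, ksk = make_kswitch_key(ring_automorph(s, g, params), s, params))
      t <- t * 2
    }
    structure(list(backend = "toy_ckks", relin = relin, galois = galois),
              class = "he_eval_keys")
  })
}

#' Create the full key bundle for a collaboration
#'
#' Runs the key-generation role once: master key, additive shares, public
#' and evaluation keys, and a shared 256-bit symmetric key for protecting
#' partial decryptions. Each share (and a copy of the symmetric key) is
#' sealed with authenticated encryption under a key derived from the site's
#' passphrase. The master secret key is discarded unless `keep_master` is
#' set (test oracle only).
#'
#' @param params an [he_params()] object
#' @param seed integer seed for all key material
#' @param passphrases character vector of per-site passphrases (defaults to
#'   `"site-<s>-pass"`)
#' @param keep_master retain the master key in the bundle (tests only)
#' @return an object of class `he_key_bundle`
#' @export
make_key_bundle <- function(params, seed,
                            passphrases = sprintf("site-%d-pass", seq_len(params$n_sites)),
                            keep_master = FALSE) {
  stopifnot(length(passphrases) == params$n_sites)
  msk <- generate_master_key(params, seed)
  shares <- split_secret_key(msk, params, seed + 1)
  pk <- generate_public_key(msk, params, seed + 2)
  evk <- make_eval_keys(msk, params, seed + 3)
  with_seed(seed + 4, {
    symkey <- rand_bytes(32)
    enc_shares <- lapply(seq_len(params$n_sites), function(s) {
      key <- derive_key(passphrases[s])
      aead_encrypt(key, serialize(shares[[s]], NULL),
                   aad = charToRaw(sprintf("dsk-site-%d", s)))
    })
    enc_symkeys <- lapply(seq_len(params$n_sites), function(s) {
      key <- derive_key(passphrases[s])
      aead_encrypt(key, symkey, aad = charToRaw(sprintf("symkey-site-%d", s)))
    })
    bundle <- list(params = params, public_key = pk, eval_keys = evk,
                   enc_shares = enc_shares, enc_symkeys = enc_symkeys,
                   n_sites = params$n_sites)
    if (keep_master) bundle$master_key <- msk
    structure(bundle, class = "he_key_bundle")
  })
}

#' Open one site's view of a key bundle
#'
#' Authenticates and decrypts the site's secret-key share and the shared
#' symmetric key; errors if the passphrase is wrong or the payload was
#' tampered with.
#'
#' @param bundle a `he_key_bundle`
#' @param site_id which site is opening the bundle
#' @param passphrase that site's passphrase
#' @return list with `share` (a `secret_key_share`) and `symkey` (raw)
#' @export
open_key_bundle <- function(bundle, site_id,
                            passphrase = sprintf("site-%d-pass", site_id)) {
  key <- derive_key(passphrase)
  share <- unserialize(aead_decrypt(key, bundle$enc_shares[[site_id]],
                                    aad = charToRaw(sprintf("dsk-site-%d", site_id))))
  symkey <- aead_decrypt(key, bundle$enc_symkeys[[site_id]],
                         aad = charToRaw(sprintf("symkey-site-%d", site_id)))
  list(share = share, symkey = symkey)
}

#' Write a key bundle to a directory
#'
#' Layout: `params.json`, `public.key`, `eval.keys`, `site_<s>.dsk.enc`,
#' `shared.symkey.enc`. Binary files carry a 4-byte magic and a version byte.
#' @param bundle a `he_key_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_key_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- bundle$params
  jsonlite::write_json(
    list(poly_degree = p$poly_degree, coeff_modulus_bits = p$coeff_modulus_bits,
         scale_bits = p$scale_bits, smudging_bits = p$smudging_bits,
         dsk_noise_bits = p$dsk_noise_bits, n_sites = p$n_sites,
         backend = p$backend),
    file.path(dir, "params.json"), auto_unbox = TRUE)
  write_magic_file(file.path(dir, "public.key"), "FHGK", serialize(bundle$public_key, NULL))
  write_magic_file(file.path(dir, "eval.keys"), "FHGE", serialize(bundle$eval_keys, NULL))
  for (s in seq_len(bundle$n_sites)) {
    write_magic_file(file.path(dir, sprintf("site_%d.dsk.enc", s)), "FHGS",
                     bundle$enc_shares[[s]])
  }
  write_magic_file(file.path(dir, "shared.symkey.enc"), "FHGY",
                   serialize(bundle$enc_symkeys, NULL))
  invisible(dir)
}

#' Read a key bundle from a directory written by [write_key_bundle()]
#' @param dir bundle directory
#' @return a `he_key_bundle` (without any master key)
#' @export
read_key_bundle <- function(dir) {
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- he_params(poly_degree = pj$poly_degree,
                      coeff_modulus_bits = pj$coeff_modulus_bits,
                      scale_bits = pj$scale_bits, smudging_bits = pj$smudging_bits,
                      dsk_noise_bits = pj$dsk_noise_bits, n_sites = pj$n_sites,
                      backend = pj$backend)
  pk <- unserialize(read_magic_file(file.path(dir, "public.key"), "FHGK"))
  evk <- unserialize(read_magic_file(file.path(dir, "eval.keys"), "FHGE"))
  enc_shares <- lapply(seq_len(params$n_sites), function(s) {
    read_magic_file(file.path(dir, sprintf("site_%d.dsk.enc", s)), "FHGS")
  })
  enc_symkeys <- unserialize(read_magic_file(file.path(dir, "shared.symkey.enc"), "FHGY"))
  structure(list(params = params, public_key = pk, eval_keys = evk,
                 enc_shares = enc_shares, enc_symkeys = enc_symkeys,
                 n_sites = params$n_sites),
            class = "he_key_bundle")
}
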