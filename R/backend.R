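# The ciphertext-arithmetic contract shared by the two backends. All
# operations check level/scale alignment and keep the same bookkeeping so
# the contract test-suite runs identically against both.

new_ciphertext <- function(backend, payload, level, scale, n_slots) {
  structure(list(backend = backend, payload = payload, level = level,
                 scale = scale, n_slots = n_slots),
            class = "he_ciphertext")
}

#' @export
print.he_ciphertext <- function(x, ...) {
  cat("<he_ciphertext>", x$backend, "level", x$level,
      "log2(scale)", round(log2(x$scale), 2), "slots", x$n_slots, "\n")
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(a$backend, b$backend) || a$n_slots != b$n_slots) {
    stop("alignment error: incompatible ciphertexts")
  }
  if (a$level != b$level) {
    stop("alignment error: levels differ (", a$level, " vs ", b$level,
         "); use he_level_drop")
  }
  if (abs(log2(a$scale) - log2(b$scale)) > 1e-6) {
    stop("alignment error: scales differ (2^", round(log2(a$scale), 3),
         " vs 2^", round(log2(b$scale), 3), "); use he_scale_up")
  }
}

check_budget <- function(a) {
  if (a$level < 1) {
    stop("depth error: multiplicative budget exhausted; ",
         "apply a collective refresh before multiplying")
  }
}

#' Encrypt a packed plaintext
#'
#' The toy backend performs standard randomized RLWE public-key encryption
#' (ephemeral ternary v, Gaussian errors: c0 = v*pk0 + m + e0,
#' c1 = v*pk1 + e1); the emulated backend wraps the slot values with a
#' pseudo-random whitening offset and CKKS-scale approximation noise.
#'
#' @param pt a `he_plaintext` from [he_encode()]
#' @param pk the common `he_public_key`
#' @param params an [he_params()] object
#' @return a fresh `he_ciphertext` at maximum level
#' @export
he_encrypt <- function(pt, pk, params) {
  if (length(pt$slots) != params$slot_size) {
    stop("capacity error: plaintext has ", length(pt$slots),
         " slots, params expect ", params$slot_size)
  }
  if (params$backend == "toy_ckks") toy_encrypt(pt, pk, params)
  else em_encrypt(pt, params)
}

#' Elementwise homomorphic addition and subtraction
#' @param a,b ciphertexts at equal level and scale
#' @return a `he_ciphertext`; level and scale unchanged
#' @export
he_add <- function(a, b) {
  check_aligned(a, b)
  if (a$backend == "toy_ckks") toy_add(a, b) else em_add(a, b)
}

#' @rdname he_add
#' @export
he_sub <- function(a, b) {
  check_aligned(a, b)
  if (a$backend == "toy_ckks") toy_sub(a, b) else em_sub(a, b)
}

#' Elementwise homomorphic multiplication
#'
#' Consumes one multiplicative level; the toy backend relinearizes the
#' tensor ciphertext with the relinearization key. The result scale is the
#' product of the operand scales (single-modulus bookkeeping: no rescaling
#' division takes place).
#'
#' @param a,b ciphertexts at equal level and scale
#' @param evk evaluation keys from the bundle
#' @param params an [he_params()] object
#' @return a `he_ciphertext` at `level - 1`
#' @export
he_mul <- function(a, b, evk, params) {
  check_aligned(a, b)
  check_budget(a)
  if (a$backend == "toy_ckks") toy_mul(a, b, evk, params) else em_mul(a, b)
}

#' Multiply a ciphertext by a packed plaintext
#' @param a a ciphertext
#' @param pt a `he_plaintext`
#' @param params an [he_params()] object
#' @return a `he_ciphertext` at `level - 1`, scale multiplied by `pt$scale`
#' @export
he_mul_plain <- function(a, pt, params) {
  check_budget(a)
  if (a$backend == "toy_ckks") toy_mul_plain(a, pt, params)
  else em_mul_plain(a, pt)
}

#' Rotate ciphertext slots circularly left
#'
#' @param a a ciphertext
#' @param t rotation amount (0 <= t < slot count); arbitrary amounts are
#'   composed from power-of-two Galois keys on the toy backend
#' @param evk evaluation keys
#' @param params an [he_params()] object
#' @param count_as instrumentation class for the rotation budget counters
#' @return the rotated `he_ciphertext`; level unchanged
#' @export
he_rotate <- function(a, t, evk, params, count_as = "alignment") {
  t <- ((t %% a$n_slots) + a$n_slots) %% a$n_slots
  if (t == 0) return(a)
  count_rotation(count_as)
  if (a$backend == "toy_ckks") toy_rotate(a, t, evk, params)
  else em_rotate(a, t)
}

#' Multiply a ciphertext by an exact power of two
#'
#' Integer scalar multiplication used to align scales before addition; does
#' not consume a level (no relinearization is needed).
#' @param a a ciphertext
#' @param log2_factor non-negative integer k; the value scale becomes
#'   `scale * 2^k` so decoded values are unchanged
#' @param params an [he_params()] object
#' @return a `he_ciphertext`
#' @export
he_scale_up <- function(a, log2_factor, params) {
  if (log2_factor == 0) return(a)
  if (a$backend == "toy_ckks") {
    a$payload$c0 <- ring_scale_pow2(a$payload$c0, log2_factor, params)
    a$payload$c1 <- ring_scale_pow2(a$payload$c1, log2_factor, params)
  }
  a$scale <- a$scale * 2^log2_factor
  a
}

#' Drop the recorded level of a ciphertext (modulus-switch analogue)
#' @param a a ciphertext
#' @param level target level, at most the current one
#' @return a `he_ciphertext` at the requested level
#' @export
he_level_drop <- function(a, level) {
  if (level > a$level) stop("alignment error: cannot raise a level")
  a$level <- level
  a
}

#' Compute one site's partial decryption of a ciphertext
#'
#' Toy backend: `(c1 * dsk_s + e_sm) mod q`, plus `c0` iff `include_c0`;
#' `e_sm` is the smudging noise with variance `2^smudging_bits` at the ring
#' layer. Emulated backend: an additive pseudo-random share of the slot
#' values plus smudging perturbation of sd
#' `2^(smudging_bits/2 - scale_bits)` per slot.
#'
#' @param ct a ciphertext
#' @param share the site's `secret_key_share`
#' @param params an [he_params()] object
#' @param include_c0 exactly one site per aggregation sets this
#' @param seed optional seed for the smudging noise
#' @return a `partial_decryption` object
#' @export
partial_decrypt <- function(ct, share, params, include_c0 = FALSE, seed = NULL) {
  f <- function() {
    if (ct$backend == "toy_ckks") toy_partial_decrypt(ct, share, params, include_c0)
    else em_partial_decrypt(ct, share, params, include_c0)
  }
  if (is.null(seed)) f() else with_seed(seed, f())
}

#' Aggregate partial decryptions into the decoded plaintext
#'
#' Requires one partial per site with exactly one including the c0 term;
#' the modular sum is center-lifted and decoded.
#' @param partials list of `partial_decryption` objects
#' @param params an [he_params()] object
#' @return a `he_plaintext` whose slots hold the decoded values
#' @export
aggregate_partials <- function(partials, params) {
  if (length(partials) != params$n_sites) {
    stop("incompleteness error: have ", length(partials),
         " partial decryptions, need one from each of ", params$n_sites, " sites")
  }
  nc0 <- sum(vapply(partials, function(p) isTRUE(p$includes_c0), logical(1)))
  if (nc0 != 1) {
    stop("protocol error: exactly one partial decryption must include c0 (got ",
         nc0, ")")
  }
  if (partials[[1]]$backend == "toy_ckks") toy_aggregate(partials, params)
  else em_aggregate(partials, params)
}

#' Decrypt with the master secret key (test oracle)
#'
#' Only usable when the bundle was created with `keep_master = TRUE`; the
#' protocol itself never holds the master key.
#' @param ct a ciphertext
#' @param msk the retained `master_secret_key`
#' @param params an [he_params()] object
#' @return numeric vector of decoded slot values
#' @export
he_decrypt_master <- function(ct, msk, params) {
  if (ct$backend == "toy_ckks") {
    m <- ring_add(ct$payload$c0, ring_mul(ct$payload$c1, msk$res, params), params)
    decode_from_ring(ring_center(m, params), ct$scale, params)
  } else {
    em_values(ct)
  }
}
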