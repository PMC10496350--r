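#' Encryption parameters
#'
#' Bundles the CKKS-style scheme parameters shared by all sites. The ring
#' degree `poly_degree` (n, a power of 2) fixes the slot capacity at n/2
#' packed reals per ciphertext. `coeff_modulus_bits` describes the
#' coefficient modulus: the toy RLWE backend collapses the vector to a single
#' modulus q whose bit length is `sum(coeff_modulus_bits)` (capped at 100
#' bits), and the multiplicative depth budget of both backends is
#' `length(coeff_modulus_bits) - 1`. `scale_bits` is the binary log of the
#' CKKS encoding scale; `smudging_bits` is the binary log of the *variance*
#' of the smudging noise added to every partial decryption (default 40);
#' `dsk_noise_bits` is the binary log of the variance of the Gaussian noise
#' in the additive secret-key shares.
#'
#' @param poly_degree ring degree n, a power of two
#' @param coeff_modulus_bits integer vector of modulus bit sizes
#' @param scale_bits encoding scale exponent (scale = 2^scale_bits)
#' @param smudging_bits smudging noise variance exponent, >= 0
#' @param dsk_noise_bits secret-share noise variance exponent
#' @param n_sites number of collaborating sites S >= 1
#' @param backend `"emulated"` (plaintext slot vectors with CKKS semantics)
#'   or `"toy_ckks"` (real single-modulus RLWE at small n)
#' @param ks_base_bits digit width of the key-switching decomposition; the
#'   key-switch noise grows with 2^ks_base_bits, so 4 keeps rotation error
#'   well below the encoding resolution at scale 2^30
#' @return an object of class `he_params`
#' @examples
#' p <- he_params(poly_degree = 64, n_sites = 3, backend = "toy_ckks")
#' p$slot_size  # 32
#' @export
he_params <- function(poly_degree = 16384,
                      coeff_modulus_bits = c(60, 40, 40, 40, 40, 40, 40, 60),
                      scale_bits = 30,
                      smudging_bits = 40,
                      dsk_noise_bits = 20,
                      n_sites = 3,
                      backend = c("emulated", "toy_ckks"),
                      ks_base_bits = 4) {
  backend <- match.arg(backend)
  if (!is_pow2(poly_degree)) {
    stop("parameter error: poly_degree must be a power of 2, got ", poly_degree)
  }
  if (length(coeff_modulus_bits) < 1 || any(coeff_modulus_bits <= 0)) {
    stop("parameter error: coeff_modulus_bits must be positive")
  }
  if (smudging_bits < 0) stop("parameter error: smudging_bits must be >= 0")
  if (n_sites < 1) stop("parameter error: n_sites must be >= 1")
  qbits <- min(sum(coeff_modulus_bits), 100)
  p <- list(
    poly_degree = as.integer(poly_degree),
    slot_size = as.integer(poly_degree / 2),
    coeff_modulus_bits = as.integer(coeff_modulus_bits),
    qbits = qbits,
    scale_bits = scale_bits,
    scale = 2^scale_bits,
    smudging_bits = smudging_bits,
    dsk_noise_bits = dsk_noise_bits,
    n_sites = as.integer(n_sites),
    max_level = length(coeff_modulus_bits) - 1L,
    backend = backend,
    err_sd = 3.2,          # fresh RLWE error
    ks_base_bits = as.integer(ks_base_bits)
  )
  # the ring modulus is needed by the keys module for both backends
  p$primes <- find_ntt_primes_cpp(qbits, p$poly_degree)
  p$ks_ndigits <- as.integer(ceiling(qbits / p$ks_base_bits) + 1L)
  class(p) <- "he_params"
  p
}

#' @export
print.he_params <- function(x, ...) {
  cat("<he_params>", x$backend, "n =", x$poly_degree,
      "slots =", x$slot_size, "depth =", x$max_level,
      "scale = 2^", x$scale_bits, "smudging = 2^", x$smudging_bits, "\n")
  invisible(x)
}

# small toy parameter set used throughout the unit tests: full RLWE pipeline
# at desk scale
toy_test_params <- function(n = 64, n_sites = 3, scale_bits = 30,
                            coeff_modulus_bits = c(34, 33, 33),
                            smudging_bits = 40, ...) {
  he_params(poly_degree = n, coeff_modulus_bits = coeff_modulus_bits,
            scale_bits = scale_bits, smudging_bits = smudging_bits,
            n_sites = n_sites, backend = "toy_ckks", ...)
}
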