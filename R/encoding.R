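# CKKS encoding via the canonical embedding. Slots are the evaluations of
# the (real-coefficient) ring element at n/2 primitive 2n-th roots of unity,
# ordered along the orbit of 5 so that the Galois automorphism x -> x^(5^t)
# rotates the slot vector left by t.

embedding_matrix <- function(n) {
  key <- paste0("emb", n)
  if (!is.null(.fhg[[key]])) return(.fhg[[key]])
  half <- n / 2
  e <- numeric(half)
  e[1] <- 1
  for (j in seq_len(half - 1)) e[j + 1] <- (e[j] * 5) %% (2 * n)
  # W[j, k] = omega_j^k with omega_j = exp(i*pi*e_j/n)
  W <- exp(1i * pi * outer(e, 0:(n - 1)) / n)
  .fhg[[key]] <- W
  W
}

# real slot vector (length n/2) -> real coefficient vector (length n)
embed_encode <- function(v, n) {
  W <- embedding_matrix(n)
  (2 / n) * Re(crossprod(Conj(W), v))[, 1]
}

# real coefficient vector -> slot vector
embed_decode <- function(p, n) {
  W <- embedding_matrix(n)
  Re(W %*% p)[, 1]
}

#' Encode a vector of reals into a packed plaintext
#'
#' Pads `values` with zeros to the slot capacity (n/2) and attaches the
#' encoding scale. The toy backend turns this into ring coefficients at
#' encryption time; the emulated backend uses the slots directly.
#'
#' @param values numeric vector, length at most `params$slot_size`
#' @param params an [he_params()] object
#' @param scale encoding scale; defaults to 2^scale_bits
#' @return a `he_plaintext` with fields `slots` and `scale`
#' @export
he_encode <- function(values, params, scale = params$scale) {
  if (length(values) > params$slot_size) {
    stop("capacity error: ", length(values), " values exceed slot size ",
         params$slot_size)
  }
  slots <- c(as.numeric(values), numeric(params$slot_size - length(values)))
  structure(list(slots = slots, scale = scale), class = "he_plaintext")
}

#' Decode a packed plaintext back to a vector of reals
#' @param pt a `he_plaintext`
#' @return numeric vector of slot values
#' @export
he_decode <- function(pt) pt$slots

# toy backend: plaintext -> ring coefficients (rounded), as residues
encode_to_ring <- function(pt, params) {
  coeff <- round(embed_encode(pt$slots * pt$scale, params$poly_degree))
  ring_from_int(coeff, params)
}

# centered ring coefficients -> slot values at given scale
decode_from_ring <- function(centered, scale, params) {
  embed_decode(centered / scale, params$poly_degree)
}
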